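#' Well coordinate helpers
#'
#' Microplate wells are written letter+number ("A1".."H12" on a 96-well
#' plate). Internally they are 0-based (row, col) pairs so grids can be
#' indexed directly; all files use the letter+number dialect.
#'
#' @param well character vector of well labels such as "A1" or "H12".
#' @param n_rows,n_cols plate geometry (default 8 x 12, a 96-well plate).
#' @return `well_to_index()` returns a two-column integer matrix (row, col),
#'   0-based. `index_to_well()` returns a character vector of labels.
#' @examples
#' well_to_index("B3")          # row 1, col 2
#' index_to_well(0L, 0L)        # "A1"
#' @export
well_to_index <- function(well, n_rows = 8L, n_cols = 12L) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-Z][0-9]+$", well)
  if (!all(ok)) {
    stop("malformed well label(s): ", paste(unique(well[!ok]), collapse = ", "))
  }
  row <- match(substr(well, 1L, 1L), LETTERS) - 1L
  col <- as.integer(sub("^[A-Z]", "", well)) - 1L
  bad <- row >= n_rows | col >= n_cols | col < 0L
  if (any(bad)) {
    stop("well label(s) outside ", n_rows, "x", n_cols, " plate: ",
         paste(unique(well[bad]), collapse = ", "))
  }
  cbind(row = row, col = col)
}

#' @rdname well_to_index
#' @param row,col 0-based integer coordinates.
#' @export
index_to_well <- function(row, col) {
  paste0(LETTERS[row + 1L], col + 1L)
}

#' All well labels of a plate in row-major order
#' @inheritParams well_to_index
#' @return character vector of length `n_rows * n_cols`.
#' @export
plate_wells <- function(n_rows = 8L, n_cols = 12L) {
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
}

# Valid layout roles, in canonical order. neg_control is mutant construct +
# non-targeting siRNA (activity 1 by definition after normalization);
# pos_control is mutant + CASP3 siRNA; the two tox_control roles carry the
# wild-type-length construct.
.roles <- c("test", "neg_control", "pos_control",
            "tox_control_nt", "tox_control_casp3")

#' @keywords internal
assert_roles <- function(role) {
  bad <- setdiff(unique(role), .roles)
  if (length(bad)) {
    stop("unknown layout role(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.roles, collapse = ", "), ")")
  }
  invisible(role)
}
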