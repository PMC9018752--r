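# Internal helpers.

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Atomic CSV write: write to a temp file in the target directory, then rename.
write_csv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  readr::write_csv(df, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_csv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# 16 x 24 plate geometry ---------------------------------------------------

.plate_rows <- LETTERS[1:16]

well_id <- function(row, col) paste0(.plate_rows[row], col)

# Inner region of a 384-well plate: the outermost two rows and columns are
# buffer wells, leaving 12 x 20 = 240 usable wells.
inner_wells <- function() {
  grid <- expand.grid(row = 3:14, col = 3:22)
  # column-major order: fill down each column, left to right
  grid <- grid[order(grid$col, grid$row), ]
  well_id(grid$row, grid$col)
}
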