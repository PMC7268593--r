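# shared helpers: FFT grids, sorting, hashing, logging

# circular shift of a matrix by (dr, dc) (toward higher indices)
roll2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- ((dr %% nr) + nr) %% nr
  dc <- ((dc %% nc) + nc) %% nc
  if (dr > 0) m <- rbind(m[(nr - dr + 1):nr, , drop = FALSE], m[1:(nr - dr), , drop = FALSE])
  if (dc > 0) m <- cbind(m[, (nc - dc + 1):nc, drop = FALSE], m[, 1:(nc - dc), drop = FALSE])
  m
}

# move DC (index 1,1) to the array center; inverse undoes it for odd sizes
fftshift2 <- function(m) roll2(m, floor(nrow(m) / 2), floor(ncol(m) / 2))
ifftshift2 <- function(m) roll2(m, ceiling(nrow(m) / 2), ceiling(ncol(m) / 2))

# frequency values (rad per sample unit d) in native FFT bin order
fft_kvals <- function(n, d = 1) {
  j <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  2 * pi * j / (n * d)
}

# shifted bin offsets from DC, matching fftshift2 layout
shifted_bins <- function(n) seq_len(n) - 1L - floor(n / 2)

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# numeric-aware ("natural") order of file names: img_2 sorts before img_10
natural_order <- function(x) {
  xs <- tolower(basename(x))
  parts <- regmatches(xs, gregexpr("[0-9]+|[^0-9]+", xs))
  maxlen <- max(lengths(parts))
  keys <- lapply(seq_len(maxlen), function(i) {
    piece <- vapply(parts, function(p) if (i <= length(p)) p[i] else "", "")
    num <- suppressWarnings(as.numeric(piece))
    if (all(is.na(num) | piece == "")) piece else {
      # numeric chunks sort by value, padded to fixed width
      ifelse(is.na(num), piece, sprintf("%020.0f", num))
    }
  })
  do.call(order, keys)
}

# md5 of a file's content (hex string)
file_md5 <- function(path) unname(tools::md5sum(path))

# md5 of a character string
text_md5 <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(paste(txt, collapse = "\n"), f, eos = NULL, useBytes = TRUE)
  file_md5(f)
}

# content hash of an input (file or directory), first `digits` hex digits
dataset_identifier <- function(path, digits = 5L) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE, recursive = TRUE)
    files <- files[natural_order(files)]
    h <- text_md5(paste(unname(tools::md5sum(files)), collapse = ""))
  } else {
    h <- file_md5(path)
  }
  substr(h, 1L, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sp_log <- function(state, stage, ...) {
  msg <- sprintf("[%s] [%s] %s", state$dataset_id %||% "-----", stage,
                 paste0(..., collapse = ""))
  message(msg)
  if (!is.null(state$results_dir) && dir.exists(state$results_dir)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n", sep = "",
        file = file.path(state$results_dir, "pipeline.log"), append = TRUE)
  }
  invisible(msg)
}
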