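#' Cross-spectral density container
#'
#' Holds a two-channel cross-spectral density: a strictly increasing
#' frequency grid and one Hermitian 2 x 2 complex matrix per frequency, plus
#' subject/condition metadata. The diagonal (auto-spectra) must be real and
#' nonnegative.
#'
#' @param freq Frequency grid (Hz), strictly increasing.
#' @param csd Complex array `2 x 2 x length(freq)`.
#' @param subject Subject identifier (optional).
#' @param condition One of `"pre"`, `"bolus"`, `"infusion"` (optional).
#' @return An object of class `spectral_data`.
#' @export
spectral_data <- function(freq, csd, subject = NA, condition = NA) {
  freq <- as.numeric(freq)
  if (any(diff(freq) <= 0)) stop("frequency grid must be strictly increasing",
                                 call. = FALSE)
  if (!is.array(csd) || !identical(dim(csd), c(2L, 2L, length(freq)))) {
    stop("csd must be a 2 x 2 x length(freq) array", call. = FALSE)
  }
  storage.mode(csd) <- "complex"
  herm_err <- max(abs(csd[1, 2, ] - Conj(csd[2, 1, ])))
  scale <- max(abs(csd), 1e-300)
  if (herm_err > 1e-6 * scale) {
    stop("cross-spectral matrix is not Hermitian", call. = FALSE)
  }
  if (max(abs(Im(csd[1, 1, ])), abs(Im(csd[2, 2, ]))) > 1e-6 * scale ||
      min(Re(csd[1, 1, ]), Re(csd[2, 2, ])) < -1e-6 * scale) {
    stop("auto-spectra must be real and nonnegative", call. = FALSE)
  }
  if (!is.na(condition) &&
      !condition %in% c("pre", "bolus", "infusion")) {
    stop("condition must be one of pre/bolus/infusion", call. = FALSE)
  }
  structure(list(freq = freq, csd = csd, subject = subject,
                 condition = condition),
            class = "spectral_data")
}

#' @export
print.spectral_data <- function(x, ...) {
  cat("<spectral_data> 2 x 2 CSD on ", length(x$freq), " frequencies [",
      min(x$freq), "-", max(x$freq), " Hz]", sep = "")
  if (!is.na(x$subject)) cat("  subject:", x$subject)
  if (!is.na(x$condition)) cat("  condition:", x$condition)
  cat("\n")
  invisible(x)
}

#' Tidy a spectral_data object into a long tibble
#'
#' One row per frequency and matrix entry, with real and imaginary parts.
#'
#' @param x A `spectral_data` object.
#' @param ... Unused.
#' @export
tidy.spectral_data <- function(x, ...) {
  entries <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  purrr::map_dfr(entries, function(e) {
    v <- x$csd[e[1], e[2], ]
    tibble::tibble(
      frequency = x$freq, row = e[1], col = e[2],
      re = Re(v), im = Im(v),
      subject = x$subject, condition = x$condition
    )
  })
}

#' Map a CSD to its real feature vector
#'
#' Concatenates real and imaginary parts of the upper-triangular CSD entries
#' (both auto-spectra and the off-diagonal) across frequencies, giving a
#' vector of length `6 * length(freq)`: imaginary parts of the (real)
#' diagonals are carried as explicit zeros so the map is invertible up to
#' Hermitian symmetry. A scalar scaling can be applied and is stored as an
#' attribute so inversions can undo it.
#'
#' @param x A `spectral_data` object.
#' @param scale Scalar multiplier applied to all features.
#' @return Numeric feature vector with attributes `freq` (frequency of each
#'   entry) and `scale`.
#' @export
featurize <- function(x, scale = 1) {
  stopifnot(inherits(x, "spectral_data"))
  if (any(!is.finite(Re(x$csd))) || any(!is.finite(Im(x$csd)))) {
    stop("NaN/Inf in cross-spectral density", call. = FALSE)
  }
  s11 <- x$csd[1, 1, ]; s12 <- x$csd[1, 2, ]; s22 <- x$csd[2, 2, ]
  v <- c(Re(s11), Im(s11), Re(s12), Im(s12), Re(s22), Im(s22)) * scale
  structure(v, freq = rep(x$freq, 6), scale = scale)
}

#' Reconstruct a spectral_data object from its feature vector
#'
#' Inverse of [featurize()] up to Hermitian symmetry.
#'
#' @param v Feature vector as produced by [featurize()].
#' @param freq Frequency grid of the original object.
#' @param scale The scaling used in [featurize()].
#' @inheritParams spectral_data
#' @export
defeaturize <- function(v, freq, scale = attr(v, "scale") %||% 1,
                        subject = NA, condition = NA) {
  nf <- length(freq)
  stopifnot(length(v) == 6 * nf)
  v <- as.numeric(v) / scale
  part <- function(k) v[((k - 1) * nf + 1):(k * nf)]
  s11 <- complex(real = part(1), imaginary = part(2))
  s12 <- complex(real = part(3), imaginary = part(4))
  s22 <- complex(real = part(5), imaginary = part(6))
  csd <- array(NA_complex_, c(2, 2, nf))
  csd[1, 1, ] <- Re(s11); csd[2, 2, ] <- Re(s22)
  csd[1, 2, ] <- s12; csd[2, 1, ] <- Conj(s12)
  spectral_data(freq, csd, subject = subject, condition = condition)
}

#' Write/read a spectral_data object as delimited text
#'
#' The exchange format is a tab-separated table with one row per frequency
#' and columns for the real and imaginary parts of the four matrix entries;
#' subject and condition ride along as `#`-prefixed header lines.
#'
#' @param x A `spectral_data` object.
#' @param path File path.
#' @export
write_spectral_data <- function(x, path) {
  stopifnot(inherits(x, "spectral_data"))
  df <- data.frame(
    frequency = x$freq,
    re11 = Re(x$csd[1, 1, ]), im11 = Im(x$csd[1, 1, ]),
    re12 = Re(x$csd[1, 2, ]), im12 = Im(x$csd[1, 2, ]),
    re21 = Re(x$csd[2, 1, ]), im21 = Im(x$csd[2, 1, ]),
    re22 = Re(x$csd[2, 2, ]), im22 = Im(x$csd[2, 2, ])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# subject: ", x$subject),
               paste0("# condition: ", x$condition)), con)
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectral_data
#' @export
read_spectral_data <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    val <- sub(paste0("^# ", key, ": "), "", ln[1])
    if (val == "NA") NA else val
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  csd <- array(NA_complex_, c(2, 2, nrow(df)))
  csd[1, 1, ] <- complex(real = df$re11, imaginary = df$im11)
  csd[1, 2, ] <- complex(real = df$re12, imaginary = df$im12)
  csd[2, 1, ] <- complex(real = df$re21, imaginary = df$im21)
  csd[2, 2, ] <- complex(real = df$re22, imaginary = df$im22)
  spectral_data(df$frequency, csd, subject = meta("subject"),
                condition = meta("condition"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
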