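# Reading raw DEER records (Bruker BES3T and plain ASCII), phase
# correction, zero-time location, and conversion to normalized
# dipolar traces ready for fitting.

#' Raw DEER record
#'
#' A recorded echo decay before pre-processing: time axis in us, real and
#' (optionally) imaginary channel, plus provenance.
#'
#' @param time_us Strictly increasing acquisition times (us).
#' @param signal_real Real channel, same length as `time_us`.
#' @param signal_imag Optional imaginary channel.
#' @param source_path Provenance string.
#' @param meta Free-form key/value acquisition metadata.
#' @return Object of class `raw_record`.
#' @export
raw_record <- function(time_us, signal_real, signal_imag = NULL,
                       source_path = "", meta = list()) {
  time_us <- as.numeric(time_us)
  signal_real <- as.numeric(signal_real)
  n <- length(time_us)
  if (n < 4L) stop("a raw record needs at least 4 points")
  if (any(!is.finite(time_us)) || any(diff(time_us) <= 0))
    stop("time axis must be finite and strictly increasing")
  if (length(signal_real) != n)
    stop("real channel length (", length(signal_real),
         ") does not match time axis length (", n, ")")
  if (!is.null(signal_imag)) {
    signal_imag <- as.numeric(signal_imag)
    if (length(signal_imag) != n)
      stop("imaginary channel length does not match time axis length")
  }
  structure(list(time = time_us, real = signal_real, imag = signal_imag,
                 source_path = source_path, meta = meta),
            class = "raw_record")
}

#' @export
print.raw_record <- function(x, ...) {
  cat("<raw_record> ", length(x$time), " points, t = [",
      format(x$time[1]), ", ", format(x$time[length(x$time)]), "] us, ",
      if (is.null(x$imag)) "real" else "complex",
      if (nzchar(x$source_path)) paste0(", from ", x$source_path) else "",
      "\n", sep = "")
  invisible(x)
}

# ---- BES3T ------------------------------------------------------------

parse_dsc <- function(dsc_path) {
  lines <- readLines(dsc_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "*") &
                   !startsWith(lines, "#") & !startsWith(lines, ".DVC")]
  kv <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    key <- tok[1L]
    val <- paste(tok[-1L], collapse = " ")
    if (!is.null(kv[[key]]) && !identical(kv[[key]], val))
      stop("contradictory descriptor field '", key, "' in ", dsc_path)
    kv[[key]] <- val
  }
  kv
}

dsc_field <- function(kv, key, path) {
  v <- kv[[key]]
  if (is.null(v) || !nzchar(v))
    stop("missing descriptor field '", key, "' in ", path)
  v
}

#' Read a Bruker BES3T record (.DTA/.DSC)
#'
#' Supports one-dimensional real or complex data. The time axis is built
#' from the descriptor's XMIN/XWID/XPTS fields and converted from the
#' declared abscissa unit (ns by default) to us. The byte order follows the
#' descriptor's BSEQ flag; a payload whose size contradicts the descriptor
#' is an error, never a silent truncation.
#'
#' @param dta_path Path to the binary .DTA payload.
#' @param dsc_path Path to the .DSC descriptor; defaults to `dta_path`
#'   with its extension replaced.
#' @return A [raw_record()].
#' @export
read_bes3t <- function(dta_path, dsc_path = NULL) {
  if (is.null(dsc_path))
    dsc_path <- sub("\\.[Dd][Tt][Aa]$", ".DSC", dta_path)
  if (!file.exists(dta_path)) stop("no such file: ", dta_path)
  if (!file.exists(dsc_path)) stop("no such descriptor: ", dsc_path)
  kv <- parse_dsc(dsc_path)

  npts <- suppressWarnings(as.integer(dsc_field(kv, "XPTS", dsc_path)))
  xmin <- suppressWarnings(as.numeric(dsc_field(kv, "XMIN", dsc_path)))
  xwid <- suppressWarnings(as.numeric(dsc_field(kv, "XWID", dsc_path)))
  if (is.na(npts) || npts < 2L) stop("invalid descriptor field 'XPTS' in ", dsc_path)
  if (is.na(xmin)) stop("invalid descriptor field 'XMIN' in ", dsc_path)
  if (is.na(xwid) || xwid <= 0) stop("invalid descriptor field 'XWID' in ", dsc_path)
  ikkf <- toupper(dsc_field(kv, "IKKF", dsc_path))
  complex_data <- grepl("CPLX", ikkf)
  bseq <- toupper(if (is.null(kv[["BSEQ"]])) "BIG" else kv[["BSEQ"]])
  endian <- if (grepl("LIT", bseq)) "little" else "big"
  irfmt <- toupper(dsc_field(kv, "IRFMT", dsc_path))
  fmt <- switch(substr(irfmt, 1, 1),
                D = list(what = "double", size = 8L),
                F = list(what = "double", size = 4L),
                I = list(what = "integer", size = 4L),
                stop("unsupported descriptor field 'IRFMT' = ", irfmt,
                     " in ", dsc_path))
  xuni <- kv[["XUNI"]]
  xuni <- if (is.null(xuni)) "ns" else gsub("'", "", xuni)
  scale <- switch(tolower(xuni),
                  ns = 1e-3, us = 1, "µs" = 1, s = 1e6,
                  stop("unsupported abscissa unit in descriptor field 'XUNI': ",
                       xuni))

  nval <- npts * (if (complex_data) 2L else 1L)
  expected <- nval * fmt$size
  actual <- file.size(dta_path)
  if (actual != expected)
    stop("corrupt BES3T file ", dta_path, ": descriptor declares ", npts,
         " points (", expected, " bytes) but payload has ", actual, " bytes")
  con <- file(dta_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = fmt$what, n = nval, size = fmt$size,
               endian = endian)
  v <- as.numeric(v)

  t_us <- (xmin + xwid * (seq_len(npts) - 1) / (npts - 1)) * scale
  if (complex_data) {
    raw_record(t_us, v[seq(1L, nval, by = 2L)], v[seq(2L, nval, by = 2L)],
               source_path = dta_path, meta = kv)
  } else {
    raw_record(t_us, v, source_path = dta_path, meta = kv)
  }
}

#' Write a record as a BES3T .DTA/.DSC pair
#'
#' Big-endian float64 payload; abscissa stored in ns. Mainly used to build
#' round-trip fixtures and to export simulated data in instrument format.
#'
#' @param record A [raw_record()].
#' @param base_path Path without extension; `.DTA` and `.DSC` are appended.
#' @return Invisibly, the two paths written.
#' @export
write_bes3t <- function(record, base_path) {
  stopifnot(inherits(record, "raw_record"))
  n <- length(record$time)
  t_ns <- record$time * 1e3
  dsc <- c("#DESC 1.2 * DESCRIPTOR INFORMATION ***********************",
           "DSRC EXP",
           "BSEQ BIG",
           paste("IKKF", if (is.null(record$imag)) "REAL" else "CPLX"),
           "XTYP IDX", "YTYP NODATA", "ZTYP NODATA",
           "IRFMT D",
           if (!is.null(record$imag)) "IIFMT D",
           paste("XPTS", n),
           paste("XMIN", sprintf("%.10f", t_ns[1L])),
           paste("XWID", sprintf("%.10f", t_ns[n] - t_ns[1L])),
           "XUNI 'ns'")
  dta_path <- paste0(base_path, ".DTA")
  dsc_path <- paste0(base_path, ".DSC")
  writeLines(dsc, dsc_path)
  v <- if (is.null(record$imag)) record$real
       else as.vector(rbind(record$real, record$imag))
  con <- file(dta_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 8L, endian = "big")
  invisible(c(dta = dta_path, dsc = dsc_path))
}

# ---- ASCII ------------------------------------------------------------

#' Read a 2- or 3-column ASCII trace
#'
#' Whitespace-separated columns: time (us), real signal, optional
#' imaginary signal. Lines starting with `#` and blank lines are skipped.
#'
#' @param path File path.
#' @return A [raw_record()].
#' @export
read_ascii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^[ \t]*#", lines))
  if (length(keep) < 2L) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[keep]), "[ \t,]+")
  ncols <- lengths(rows)
  if (any(ncols < 2L))
    stop("fewer than 2 columns at line ", keep[which(ncols < 2L)[1L]],
         " of ", path)
  nc <- min(ncols)
  if (nc > 3L) nc <- 3L
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[seq_len(nc)]), numeric(nc)))
  bad <- which(colSums(!is.finite(vals)) > 0)
  if (length(bad))
    stop("non-numeric value at line ", keep[bad[1L]], " of ", path)
  vals <- t(vals)
  raw_record(vals[, 1L], vals[, 2L],
             if (nc >= 3L) vals[, 3L] else NULL,
             source_path = path)
}

#' Write a record or trace as ASCII
#'
#' Columns: time (us), real signal, optional imaginary signal, written at
#' full double precision so a read/write round trip is value-exact.
#'
#' @param x A [raw_record()] or [dipolar_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ascii <- function(x, path) {
  if (inherits(x, "dipolar_trace")) {
    tm <- x$t; re <- x$V; im <- NULL
    hdr <- "# t_us V"
  } else if (inherits(x, "raw_record")) {
    tm <- x$time; re <- x$real; im <- x$imag
    hdr <- if (is.null(im)) "# t_us V_real" else "# t_us V_real V_imag"
  } else stop("x must be a raw_record or dipolar_trace")
  body <- if (is.null(im)) sprintf("%.17g %.17g", tm, re)
          else sprintf("%.17g %.17g %.17g", tm, re, im)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- Pre-processing ---------------------------------------------------

#' Phase-correct a complex record
#'
#' Finds the rotation angle phi minimizing the sum of squared imaginary
#' parts over the last three quarters of the trace (closed form from the
#' quadratic in cos/sin), with the sign fixed so the real part near zero
#' time is positive. Real-only records pass through with phi = 0.
#'
#' @param record A [raw_record()].
#' @return List with elements `record` (rotated) and `phase_angle`
#'   (radians, in (-pi, pi\]).
#' @export
phase_correct <- function(record) {
  stopifnot(inherits(record, "raw_record"))
  if (is.null(record$imag))
    return(list(record = record, phase_angle = 0))
  n <- length(record$time)
  idx <- seq.int(floor(n / 4) + 1L, n)
  x <- record$real[idx]; y <- record$imag[idx]
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  phi <- 0.5 * atan2(-2 * sxy, sxx - syy)
  imag_energy <- function(p) {
    cp <- cos(p); sp <- sin(p)
    syy * cp^2 + 2 * sxy * sp * cp + sxx * sp^2
  }
  if (imag_energy(phi + pi / 2) < imag_energy(phi)) phi <- phi + pi / 2
  z <- complex(real = record$real, imaginary = record$imag) * exp(1i * phi)
  k <- seq_len(min(5L, n))
  if (mean(Re(z)[k]) < 0) {
    phi <- phi + pi
    z <- -z
  }
  phi <- ((phi + pi) %% (2 * pi)) - pi
  if (phi == -pi) phi <- pi
  rec <- record
  rec$real <- Re(z)
  rec$imag <- Im(z)
  list(record = rec, phase_angle = phi)
}

#' Locate the dipolar-evolution zero time
#'
#' The zero time is where the refocused echo signal is most symmetric.
#' Candidate positions on the sampling grid near the (lightly smoothed)
#' maximum are scored by the mean squared asymmetry
#' sum over tau of \[V(t0 + tau) - V(t0 - tau)\]^2 in a window of
#' +/- min(10 points, available range); the best grid position is refined
#' by parabolic interpolation of the score.
#'
#' @param record A [raw_record()] (real channel used).
#' @return Zero time t0 in us. Traces without an interior maximum yield a
#'   warning and t0 at the maximum.
#' @export
locate_zero_time <- function(record) {
  stopifnot(inherits(record, "raw_record"))
  V <- record$real; tt <- record$time; n <- length(V)
  Vs <- if (n >= 7L) stats::filter(V, rep(1 / 5, 5), sides = 2) else V
  Vs[is.na(Vs)] <- V[is.na(Vs)]
  im <- which.max(Vs)
  if (im == 1L || im == n) {
    warning("no interior maximum; using the maximum as zero time")
    return(tt[which.max(V)])
  }
  half <- max(10L, ceiling(n / 16))
  lo <- max(2L, im - half); hi <- min(n - 1L, im + half)
  S <- rep(NA_real_, n)
  for (j in lo:hi) {
    w <- min(10L, j - 1L, n - j)
    tau <- seq_len(w)
    S[j] <- mean((V[j + tau] - V[j - tau])^2)
  }
  j <- which.min(S)
  t0 <- tt[j]
  if (j > lo && j < hi && all(is.finite(S[(j - 1L):(j + 1L)]))) {
    den <- S[j - 1L] - 2 * S[j] + S[j + 1L]
    if (is.finite(den) && den > 0) {
      off <- 0.5 * (S[j - 1L] - S[j + 1L]) / den
      dt <- (tt[j + 1L] - tt[j - 1L]) / 2
      if (abs(off) <= 1) t0 <- tt[j] + off * dt
    }
  }
  t0
}

#' Normalized dipolar trace
#'
#' Constructor for pre-processed traces: time re-zeroed so `t[1] = 0`,
#' signal normalized so the smooth amplitude at t = 0 is one. The V(0)
#' check tolerates noise: the first sample must lie within
#' 1 +/- max(0.001, 5 * noise_sd).
#'
#' @param t Time (us), strictly increasing, `t[1] = 0`.
#' @param V Normalized real signal.
#' @param noise_sd Estimated per-point noise standard deviation (> 0).
#' @param pair_id Spin-label pair label, e.g. `"555/647"`.
#' @param condition_id Condition label, e.g. `"apo"` or `"ADP-Vi"`.
#' @param phase_angle Phase correction applied upstream (radians).
#' @param meta Provenance list.
#' @return Object of class `dipolar_trace`.
#' @export
dipolar_trace <- function(t, V, noise_sd, pair_id, condition_id,
                          phase_angle = 0, meta = list()) {
  t <- as.numeric(t); V <- as.numeric(V)
  n <- length(t)
  if (n < 16L) stop("a dipolar trace needs at least 16 points")
  if (length(V) != n) stop("t and V must have the same length")
  if (abs(t[1L]) > 1e-12) stop("trace time axis must start at 0")
  if (any(diff(t) <= 0)) stop("trace time axis must be strictly increasing")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  tol <- max(0.001, 5 * noise_sd)
  if (abs(V[1L] - 1) > tol)
    stop("trace is not normalized: V[1] = ", format(V[1L]),
         " deviates from 1 by more than ", format(tol))
  structure(list(t = t, V = V, noise_sd = noise_sd,
                 pair_id = as.character(pair_id),
                 condition_id = as.character(condition_id),
                 phase_angle = phase_angle, meta = meta),
            class = "dipolar_trace")
}

#' @export
print.dipolar_trace <- function(x, ...) {
  cat("<dipolar_trace> ", x$pair_id, " / ", x$condition_id, ": ",
      length(x$t), " points to ", format(max(x$t)), " us, noise sd ",
      format(signif(x$noise_sd, 3)), "\n", sep = "")
  invisible(x)
}

# Quadratic through the 3 samples nearest t0, evaluated at t0.
parabolic_value_at <- function(tt, V, t0) {
  ix <- order(abs(tt - t0))[1:3]
  ix <- sort(ix)
  X <- cbind(1, tt[ix] - t0, (tt[ix] - t0)^2)
  cf <- solve(X, V[ix])
  cf[1L]
}

#' Finalize a raw record into a dipolar trace
#'
#' Truncates to t >= t0, re-zeroes the time axis, normalizes by the
#' amplitude at t0 (parabola through the three nearest samples; if t0
#' falls between samples the interpolated point is prepended as t = 0),
#' and estimates the per-point noise from second differences of the last
#' quarter of the trace (sd of the second difference divided by sqrt(6)).
#'
#' @param record A [raw_record()] (real channel used).
#' @param t0 Zero time in us, inside the record's range.
#' @param pair_id,condition_id Labels stored on the trace.
#' @param phase_angle Phase correction applied upstream (radians).
#' @return A [dipolar_trace()].
#' @export
finalize_trace <- function(record, t0, pair_id, condition_id,
                           phase_angle = 0) {
  stopifnot(inherits(record, "raw_record"))
  tt <- record$time; V <- record$real
  if (t0 < tt[1L] || t0 > tt[length(tt)])
    stop("t0 = ", t0, " us lies outside the record's time range")
  V0 <- parabolic_value_at(tt, V, t0)
  if (!is.finite(V0) || V0 <= 0)
    stop("amplitude estimate at t0 is not positive; cannot normalize")
  eps <- 1e-9 * max(diff(tt))
  on_grid <- min(abs(tt - t0)) <= eps
  keep <- which(tt > t0 + eps)
  if (on_grid) {
    i0 <- which.min(abs(tt - t0))
    t_new <- tt[i0:length(tt)] - tt[i0]
    V_new <- V[i0:length(tt)] / V0
  } else {
    t_new <- c(0, tt[keep] - t0)
    V_new <- c(1, V[keep] / V0)
  }
  n <- length(t_new)
  if (n < 16L)
    stop("insufficient data: only ", n, " points remain after truncation")
  qidx <- seq.int(n - max(8L, floor(n / 4)) + 1L, n)
  qidx <- qidx[qidx >= 1L]
  d2 <- diff(V_new[qidx], differences = 2L)
  noise_sd <- max(sd(d2) / sqrt(6), .Machine$double.eps)
  dipolar_trace(t_new, V_new, noise_sd, pair_id, condition_id,
                phase_angle = phase_angle, meta = record$meta)
}
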