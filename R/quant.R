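# Chromatographic peak integration and the semi-quantitative
# method-validation calculations: area ratios, matrix factor, recovery,
# linearity, detection tallies.

#' SRM chromatogram
#'
#' A single transition's trace: strictly increasing time (minutes) and
#' non-negative intensities (counts) of equal length.
#'
#' @param id Transition / analyte label.
#' @param time Numeric vector, minutes, strictly increasing.
#' @param intensity Numeric vector, counts, same length, all >= 0.
#' @return A list of class `srm_chromatogram`.
#' @export
srm_chromatogram <- function(id, time, intensity) {
  if (length(time) != length(intensity)) {
    stop("time and intensity must have equal length")
  }
  if (length(time) && any(diff(time) <= 0)) {
    stop("time must be strictly increasing")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(id = id, time = as.numeric(time),
                 intensity = as.numeric(intensity)),
            class = "srm_chromatogram")
}

#' @export
print.srm_chromatogram <- function(x, ...) {
  cat("<srm_chromatogram>", x$id, "-", length(x$time), "points,",
      sprintf("%.2f-%.2f min\n", min(x$time), max(x$time)))
  invisible(x)
}

# first local minimum scanning inward from a window edge; falls back to the
# edge point when intensity is monotone into the window
.edge_min <- function(y, from_start) {
  n <- length(y)
  idx <- if (from_start) seq_len(n) else rev(seq_len(n))
  for (k in seq_len(n)) {
    i <- idx[k]
    left <- if (i > 1) y[i - 1] else Inf
    right <- if (i < n) y[i + 1] else Inf
    if (y[i] <= left && y[i] <= right) return(i)
  }
  idx[1]
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Integrate a chromatographic peak
#'
#' Stand-in for vendor peak integration (the vendor algorithm is
#' unpublished). Within the window: the apex is the maximum intensity; the
#' baseline is the straight line through the local intensity minima nearest
#' each window edge; the area is the trapezoidal integral of the
#' baseline-subtracted trace clamped at zero. A peak is flagged not-detected
#' when its baseline-corrected apex height is below `snr_mult` times the
#' median absolute deviation of the out-of-window trace (the noise
#' estimate), or when the trace carries no signal at all.
#'
#' @param chrom An `srm_chromatogram`.
#' @param window `c(start, stop)` in minutes, inside the time range, with at
#'   least 3 points.
#' @param snr_mult Detection floor multiplier (default 3).
#' @return A list of class `srm_peak`: `rt` (apex time), `area`
#'   (counts x min), `height` (baseline-corrected apex counts), `window`,
#'   `detected` (logical), `noise_mad`.
#' @export
integrate_peak <- function(chrom, window, snr_mult = 3) {
  stopifnot(inherits(chrom, "srm_chromatogram"))
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(start, stop) with start < stop")
  }
  inw <- chrom$time >= window[1] & chrom$time <= window[2]
  if (sum(inw) < 3) stop("window contains fewer than 3 samples")
  t <- chrom$time[inw]; y <- chrom$intensity[inw]

  out_y <- chrom$intensity[!inw]
  noise <- if (length(out_y) >= 3) stats::mad(out_y) else 0

  i_apex <- which.max(y)
  i_lo <- .edge_min(y, from_start = TRUE)
  i_hi <- .edge_min(y, from_start = FALSE)
  if (i_lo >= i_hi) { i_lo <- 1L; i_hi <- length(y) }
  slope <- if (t[i_hi] == t[i_lo]) 0 else
    (y[i_hi] - y[i_lo]) / (t[i_hi] - t[i_lo])
  baseline <- y[i_lo] + slope * (t - t[i_lo])
  net <- pmax(y - baseline, 0)
  area <- .trapz(t, net)
  height <- y[i_apex] - baseline[i_apex]

  detected <- height > 0 && height >= snr_mult * noise && area > 0
  if (!detected) area <- if (height <= 0) 0 else area
  structure(list(rt = t[i_apex], area = area, height = height,
                 window = window, detected = detected, noise_mad = noise),
            class = "srm_peak")
}

#' Peak-area table (analytes x samples)
#'
#' The quantitative surface of the workflow: a rectangular table of peak
#' areas with a parallel detection-flag matrix. Not-detected cells keep
#' their (usually zero) area but are marked ND and propagate as markers,
#' never as silent zeros.
#'
#' @param areas Numeric matrix, rownames = analyte ids, colnames = sample
#'   ids, all values >= 0.
#' @param detected Logical matrix of the same shape (default: all TRUE).
#' @return A `peak_area_table`.
#' @export
peak_area_table <- function(areas, detected = NULL) {
  areas <- as.matrix(areas)
  if (is.null(colnames(areas)) || (nrow(areas) > 0 && is.null(rownames(areas)))) {
    stop("areas must have analyte rownames and sample colnames")
  }
  if (any(areas < 0, na.rm = TRUE)) stop("areas must be non-negative")
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(areas), ncol(areas),
                       dimnames = dimnames(areas))
  }
  detected <- as.matrix(detected)
  if (!identical(dim(detected), dim(areas))) {
    stop("detected must match areas in shape")
  }
  dimnames(detected) <- dimnames(areas)
  structure(list(areas = areas, detected = detected),
            class = "peak_area_table")
}

#' @export
print.peak_area_table <- function(x, ...) {
  cat("<peak_area_table>", nrow(x$areas), "analytes x", ncol(x$areas),
      "samples;", sum(!x$detected), "ND cells\n")
  invisible(x)
}

#' Integrate a set of chromatograms into one sample's area column
#'
#' @param chroms List of `srm_chromatogram` objects.
#' @param windows Either one `c(start, stop)` window applied to all, or a
#'   list of windows parallel to `chroms`.
#' @param sample_id Column label for the resulting one-sample table.
#' @param snr_mult Passed to [integrate_peak()].
#' @return A `peak_area_table` with one column.
#' @export
integrate_chromatograms <- function(chroms, windows, sample_id = "sample",
                                    snr_mult = 3) {
  if (is.numeric(windows)) windows <- rep(list(windows), length(chroms))
  stopifnot(length(windows) == length(chroms))
  peaks <- mapply(integrate_peak, chroms, windows,
                  MoreArgs = list(snr_mult = snr_mult), SIMPLIFY = FALSE)
  ids <- vapply(chroms, `[[`, "", "id")
  areas <- matrix(vapply(peaks, `[[`, 0, "area"), ncol = 1,
                  dimnames = list(ids, sample_id))
  det <- matrix(vapply(peaks, `[[`, TRUE, "detected"), ncol = 1,
                dimnames = list(ids, sample_id))
  peak_area_table(areas, det)
}

#' Write / read a peak-area table as delimited text
#'
#' Tab-separated with an `analyte` column; not-detected cells are written as
#' the marker `"ND"`.
#'
#' @param tbl A `peak_area_table`.
#' @param path File path.
#' @return `path` invisibly (writer); a `peak_area_table` (reader).
#' @export
write_peak_area_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "peak_area_table"))
  chr <- matrix(as.character(tbl$areas), nrow(tbl$areas),
                dimnames = dimnames(tbl$areas))
  chr[!tbl$detected] <- "ND"
  out <- data.frame(analyte = rownames(chr), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_area_table
#' @export
read_peak_area_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  rn <- tbl$analyte
  m <- as.matrix(tbl[, setdiff(names(tbl), "analyte"), drop = FALSE])
  det <- m != "ND"
  areas <- suppressWarnings(matrix(as.numeric(m), nrow(m),
                                   dimnames = list(rn, colnames(m))))
  areas[!det] <- 0
  dimnames(det) <- dimnames(areas)
  peak_area_table(areas, det)
}

#' Area-ratio table between two samples/conditions
#'
#' Per-analyte percentage ratio `100 * numerator / denominator`, reported to
#' 3 significant figures (matching mixed reporting like 459 and 96.4).
#' Cells where the denominator is not detected or zero are returned as `NA`
#' (undefined), never as an exception or an inflated number.
#'
#' @param numerator,denominator `peak_area_table`s sharing analyte ids (and
#'   either the same sample columns or one column each).
#' @param digits Significant figures for reporting (default 3).
#' @return Numeric matrix of percentages (NA = undefined).
#' @export
area_ratio_table <- function(numerator, denominator, digits = 3) {
  stopifnot(inherits(numerator, "peak_area_table"),
            inherits(denominator, "peak_area_table"))
  common <- intersect(rownames(numerator$areas), rownames(denominator$areas))
  if (length(common) == 0) stop("no shared analyte ids")
  num <- numerator$areas[common, , drop = FALSE]
  den <- denominator$areas[common, , drop = FALSE]
  nd_num <- !numerator$detected[common, , drop = FALSE]
  nd_den <- !denominator$detected[common, , drop = FALSE]
  ratio <- signif(100 * num / den, digits)
  ratio[nd_den | den == 0] <- NA_real_
  ratio[nd_num & !nd_den & den > 0] <- 0
  ratio
}

#' Matrix factor (ionization suppression/enhancement)
#'
#' Compares three measurements of the same analyte: neat standard solution,
#' blank biological matrix, and matrix spiked with the same amount of
#' standard. The default (bioanalytically standard) reading is
#' `MF% = 100 * (spiked - matrix) / standard`: the fraction of the neat
#' response recovered on top of the endogenous background. 100% means no
#' matrix effect; 0% means full suppression. The alternate reading
#' `100 * (spiked - standard) / matrix` is selectable because the source
#' formula's fraction bar is typographically ambiguous.
#'
#' @param area_std Peak area of the neat standard.
#' @param area_matrix Peak area of the blank matrix.
#' @param area_spiked Peak area of the spiked matrix.
#' @param formula `"spike_minus_matrix_over_std"` (default) or
#'   `"spike_minus_std_over_matrix"`.
#' @return Matrix factor as a percentage.
#' @export
matrix_factor <- function(area_std, area_matrix, area_spiked,
                          formula = c("spike_minus_matrix_over_std",
                                      "spike_minus_std_over_matrix")) {
  formula <- match.arg(formula)
  if (any(c(area_std, area_matrix, area_spiked) < 0)) {
    stop("peak areas must be non-negative")
  }
  if (formula == "spike_minus_matrix_over_std") {
    if (area_std == 0) stop("zero divisor: area_std")
    100 * (area_spiked - area_matrix) / area_std
  } else {
    if (area_matrix == 0) stop("zero divisor: area_matrix")
    100 * (area_spiked - area_std) / area_matrix
  }
}

#' Recovery percentage
#'
#' `100 * processed / reference`, e.g. redissolved standard versus the
#' never-dried standard, or extracted versus neat. Reported at two decimals
#' by convention.
#'
#' @param area_processed Peak area after the processing step.
#' @param area_reference Reference peak area (> 0).
#' @return Percentage.
#' @export
recovery <- function(area_processed, area_reference) {
  if (any(area_reference <= 0)) stop("zero divisor: area_reference")
  100 * area_processed / area_reference
}

#' Calibration linearity
#'
#' Unweighted ordinary least squares of area on concentration, plus the
#' Pearson correlation coefficient r used as the linearity figure of merit.
#'
#' @param concentration Numeric vector (>= 3 distinct values).
#' @param area Numeric vector, same length.
#' @return List with `slope`, `intercept`, `r`, `r_squared`.
#' @export
linearity <- function(concentration, area) {
  stopifnot(length(concentration) == length(area))
  if (length(unique(concentration)) < 3) {
    stop("need at least 3 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration)
  r <- stats::cor(concentration, area)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2)
}

#' Detected / not-detected tallies per sample
#'
#' @param tbl A `peak_area_table`.
#' @return data.frame with columns `sample`, `detected`, `not_detected`;
#'   their sum is the analyte count for every sample.
#' @export
detection_summary <- function(tbl) {
  stopifnot(inherits(tbl, "peak_area_table"))
  det <- colSums(tbl$detected)
  nd <- colSums(!tbl$detected)
  data.frame(sample = colnames(tbl$detected),
             detected = as.integer(det),
             not_detected = as.integer(nd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write chromatograms in long delimited format
#'
#' Columns: `transition_id`, `time` (minutes), `intensity` (counts).
#'
#' @param path File path.
#' @param chroms List of `srm_chromatogram` objects (writer).
#' @return List of `srm_chromatogram` (reader); `path` invisibly (writer).
#' @export
read_chromatograms_long <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transition_id", "time", "intensity")
  if (!all(need %in% names(tbl))) {
    stop("long chromatogram file needs columns: ",
         paste(need, collapse = ", "))
  }
  ids <- unique(tbl$transition_id)
  lapply(ids, function(i) {
    sub <- tbl[tbl$transition_id == i, ]
    sub <- sub[order(sub$time), ]
    srm_chromatogram(i, sub$time, sub$intensity)
  })
}

#' @rdname read_chromatograms_long
#' @export
write_chromatograms_long <- function(chroms, path) {
  out <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(transition_id = ch$id, time = ch$time,
               intensity = ch$intensity, stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
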