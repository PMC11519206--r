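# Dataset diagnostics: descriptive statistics of sample size and
# publication year, and the corresponding histogram images.

#' Descriptive statistics of a foci dataset
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @return An object of class `cbma_dataset_stats` with fields
#'   `n_experiments`, `m_subj` (mean sample size), `m_year` (median
#'   publication year; midpoint interpolation for an even number of
#'   experiments), `subjects_list` and `years_list`.
#' @export
dataset_stats <- function(foci) {
  d <- as_foci_dataset(foci)
  if (n_experiments(d) == 0L) {
    cbma_abort("dataset contains no experiments", "cbma_empty_dataset")
  }
  subjects <- experiment_subjects(d)
  years <- experiment_years(d)
  structure(
    list(n_experiments = n_experiments(d),
         m_subj = mean(subjects),
         m_year = stats::median(years),
         subjects_list = subjects,
         years_list = years),
    class = "cbma_dataset_stats")
}

#' @export
print.cbma_dataset_stats <- function(x, ...) {
  cat(sprintf(
    "<dataset stats> %d experiments, mean sample size %.4g, median year %g\n",
    x$n_experiments, x$m_subj, x$m_year))
  invisible(x)
}

# Automatic bin rule for the top sample-size panel: Freedman-Diaconis, with
# a Sturges fallback when the IQR degenerates to zero.
auto_breaks <- function(x) {
  nb <- tryCatch(grDevices::nclass.FD(x), error = function(e) NA_integer_)
  if (!is.finite(nb) || nb < 1L) nb <- grDevices::nclass.Sturges(x)
  equal_breaks(x, max(1L, nb))
}

# Exactly `k` equal-width bins covering the data (degenerate ranges are
# widened by +/-0.5 so single-valued data still render).
equal_breaks <- function(x, k) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = k + 1L)
}

# One bin per distinct value: breaks at midpoints between sorted distinct
# values, outer edges half a step beyond.
distinct_value_breaks <- function(x) {
  v <- sort(unique(x))
  if (length(v) == 1L) return(c(v - 0.5, v + 0.5))
  mids <- (v[-1] + v[-length(v)]) / 2
  c(v[1] - (mids[1] - v[1]), mids, v[length(v)] + (v[length(v)] -
                                                   mids[length(mids)]))
}

hist_counts <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  h
}

#' Histogram diagnostics of sample size and publication year
#'
#' Writes two images. `sample_size.<ext>` stacks three histograms of the
#' per-experiment sample sizes — top: automatic binning
#' (Freedman-Diaconis, Sturges fallback); middle: exactly `sbins` bins
#' (automatic when `sbins = 0`); bottom: one bin per distinct sample-size
#' value — each with a red vertical line at the mean sample size. The
#' panels bracket coarse and maximally detailed views to guide the choice
#' of a bin width for inference. `year_of_publication.<ext>` shows the
#' publication-year histogram (one bin per calendar year; not
#' user-configurable) with a red vertical line at the median year.
#'
#' @param foci A [foci_dataset()] or path to a foci file.
#' @param sbins Number of bins of the middle sample-size histogram
#'   (0 = automatic).
#' @param outdir Output directory for the images.
#' @param format `"jpg"` (default, matching the conventional output names)
#'   or `"png"` for lossless output.
#' @return Invisibly, a list with `stats` (a [dataset_stats()] object),
#'   `images` (the two file paths) and `bins` (per-panel bin counts).
#' @export
dataset_hist <- function(foci, sbins = 0, outdir = ".",
                         format = c("jpg", "png")) {
  d <- as_foci_dataset(foci)
  format <- match.arg(format)
  sbins <- as.integer(sbins)
  if (is.na(sbins) || sbins < 0L) {
    cbma_abort("sbins must be a non-negative integer (0 = automatic)",
               "cbma_bad_arguments")
  }
  st <- dataset_stats(d)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  subj <- st$subjects_list
  h_top <- hist_counts(subj, auto_breaks(subj))
  h_mid <- hist_counts(subj, if (sbins == 0L) auto_breaks(subj) else
    equal_breaks(subj, sbins))
  h_bot <- hist_counts(subj, distinct_value_breaks(subj))
  yrs <- st$years_list
  h_year <- hist_counts(yrs, seq(min(yrs) - 0.5, max(yrs) + 0.5, by = 1))

  open_dev <- function(path) {
    if (format == "jpg") grDevices::jpeg(path, width = 800, height = 1000,
                                         quality = 95)
    else grDevices::png(path, width = 800, height = 1000)
  }
  sample_path <- file.path(outdir, paste0("sample_size.", format))
  tryCatch({
    open_dev(sample_path)
    graphics::par(mfrow = c(3, 1), mar = c(4, 4, 3, 1))
    for (h in list(h_top, h_mid, h_bot)) {
      plot(h, main = "Sample size", xlab = "Subjects", col = "grey80",
           border = "grey40")
      graphics::abline(v = st$m_subj, col = "red", lwd = 2)
    }
    grDevices::dev.off()
  }, error = function(e) {
    if (grDevices::dev.cur() > 1) grDevices::dev.off()
    cbma_abort(sprintf("cannot write '%s': %s", sample_path,
                       conditionMessage(e)), "cbma_unwritable_output")
  })

  year_path <- file.path(outdir, paste0("year_of_publication.", format))
  tryCatch({
    if (format == "jpg") grDevices::jpeg(year_path, width = 800,
                                         height = 500, quality = 95)
    else grDevices::png(year_path, width = 800, height = 500)
    graphics::par(mar = c(4, 4, 3, 1))
    plot(h_year, main = "Year of publication", xlab = "Year",
         col = "grey80", border = "grey40")
    graphics::abline(v = st$m_year, col = "red", lwd = 2)
    grDevices::dev.off()
  }, error = function(e) {
    if (grDevices::dev.cur() > 1) grDevices::dev.off()
    cbma_abort(sprintf("cannot write '%s': %s", year_path,
                       conditionMessage(e)), "cbma_unwritable_output")
  })

  invisible(list(
    stats = st,
    images = c(sample_size = sample_path, year_of_publication = year_path),
    bins = list(top = h_top$counts, middle = h_mid$counts,
                bottom = h_bot$counts, year = h_year$counts)))
}
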