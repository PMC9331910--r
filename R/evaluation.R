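#' Elementwise errors of an estimate series
#'
#' E_k = y_k - yhat_k; positive values mean the estimator underestimates.
#'
#' @param pairs a \linkS4class{PairedSeries}.
#' @return Numeric vector of errors.
#' @export
errorSeries <- function(pairs) {
  stopifnot(is(pairs, "PairedSeries"))
  pairs@truth - pairs@estimate
}

#' Root mean square error
#'
#' @param pairs a \linkS4class{PairedSeries}.
#' @return sqrt(mean((y - yhat)^2)).
#' @export
rmse <- function(pairs) {
  stopifnot(is(pairs, "PairedSeries"))
  sqrt(mean((pairs@truth - pairs@estimate)^2))
}

#' Identity-line coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with the estimates used directly (no refit).
#' Can be negative for biased estimators; no clamping is applied.
#'
#' @param pairs a \linkS4class{PairedSeries}; truth must not be constant.
#' @return Scalar R^2.
#' @export
r2Identity <- function(pairs) {
  stopifnot(is(pairs, "PairedSeries"))
  y <- pairs@truth
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) stop("truth series is constant: R^2 undefined")
  1 - sum((y - pairs@estimate)^2) / ssTot
}

#' Regression-line coefficient of determination
#'
#' Ordinary least-squares fit of the estimate on the truth; the returned
#' R^2 is the squared Pearson correlation (identical to the fit's
#' coefficient of determination). This is the agreement statistic used for
#' scatter-plot regression lines; unlike \code{\link{r2Identity}} it is
#' insensitive to a systematic affine bias.
#'
#' @param pairs a \linkS4class{PairedSeries} with at least 3 pairs.
#' @return List with \code{r2}, \code{slope}, \code{intercept}.
#' @export
r2LinearFit <- function(pairs) {
  stopifnot(is(pairs, "PairedSeries"))
  if (length(pairs@truth) < 3) stop("need at least 3 pairs for a regression")
  y <- pairs@truth
  if (sd(y) == 0) stop("truth series is constant: regression undefined")
  fit <- lm(pairs@estimate ~ y)
  list(r2 = unname(cor(y, pairs@estimate)^2),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}

.TABLE1_MD5 <- "f9cf8f4d572a5d9b51ed84c1454d1f2c"

#' Packaged per-sample reference table
#'
#' Sixteen grape samples with size errors (e_l, e_w, e_h, cm) and volumes
#' (true/reference plus the five estimators, cubic cm), transcribed
#' verbatim, together with the published Max/Min/Mean summary rows. The
#' file is checksummed; a mismatch raises a fixture-corruption error.
#'
#' @return List with \code{data} (16-row data.frame) and \code{printed}
#'   (the published Max/Min/Mean rows).
#' @export
grapeTable1 <- function() {
  path <- system.file("extdata", "grape_table1.tsv", package = "bunchmetric",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != .TABLE1_MD5)
    stop("fixture corruption: grape_table1.tsv checksum mismatch")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data <- tab[seq_len(16), ]
  data$sample <- as.integer(data$sample)
  printed <- tab[17:19, ]
  rownames(printed) <- printed$sample
  for (col in names(printed)[-1]) printed[[col]] <- as.numeric(printed[[col]])
  if (nrow(data) != 16) stop("fixture corruption: expected exactly 16 data rows")
  list(data = data, printed = printed[, -1])
}

#' Summary statistics of the packaged reference table
#'
#' Recomputes per-column max, min and mean (2 dp), each estimator's mean
#' excess over the true mean, and each estimator's regression R^2 against
#' the true volumes (4 dp), and compares them against the published summary
#' rows. Published cells that the per-sample data cannot reproduce are
#' reported as discrepancies, not hidden.
#'
#' @param fixture output of \code{\link{grapeTable1}}.
#' @return List with \code{summary} (data.frame of max/min/mean per column),
#'   \code{meanExcess} (named vector, estimator mean minus true mean),
#'   \code{r2} (named vector of regression R^2 per estimator), and
#'   \code{discrepancies} (data.frame of published vs recomputed cells that
#'   disagree beyond their printed precision).
#' @export
summarizeTable1 <- function(fixture = grapeTable1()) {
  d <- fixture$data
  cols <- setdiff(names(d), "sample")
  summary <- data.frame(
    Max = round(vapply(d[cols], max, 0), 2),
    Min = round(vapply(d[cols], min, 0), 2),
    Mean = round(vapply(d[cols], mean, 0), 2))
  volCols <- c("v_gm", "v_ch", "v_as", "v_vb", "v_pb")
  meanExcess <- round(vapply(d[volCols], mean, 0) - mean(d$v_true), 2)
  r2 <- vapply(volCols, function(cl)
    round(r2LinearFit(pairedSeries(d$v_true, d[[cl]]))$r2, 4), 0)
  names(r2) <- sub("^v_", "", volCols)
  names(meanExcess) <- names(r2)
  disc <- list()
  printed <- fixture$printed
  for (row in c("Max", "Min", "Mean")) {
    for (cl in cols) {
      pub <- printed[row, cl]
      got <- summary[cl, row]
      if (!is.na(pub) && abs(pub - got) > 0.005 + 1e-9)
        disc[[length(disc) + 1]] <- data.frame(
          row = row, column = cl, published = pub, recomputed = got)
    }
  }
  list(summary = summary,
       meanExcess = meanExcess,
       r2 = r2,
       discrepancies = if (length(disc)) do.call(rbind, disc)
                       else data.frame(row = character(0), column = character(0),
                                       published = numeric(0),
                                       recomputed = numeric(0)))
}
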