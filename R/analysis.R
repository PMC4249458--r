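## spike-train statistics: rates, ISI variability, histograms,
## autocorrelograms, and the population summaries reported by the
## experiments.

#' Mean firing rate
#'
#' @param train sorted spike times, ms.
#' @param duration recording length, ms.
#' @return rate in Hz (spike count / duration).
#' @export
meanRate <- function(train, duration) {
  if (duration <= 0) stop("duration must be > 0")
  1000 * length(train) / duration
}

#' Inter-spike intervals
#'
#' @param train sorted spike times, ms.
#' @return numeric vector of ISIs, ms (length 0 or more).
#' @export
isis <- function(train) diff(train)

#' ISI coefficient of variation
#'
#' Sample standard deviation (N-1 denominator) over mean of the inter-spike
#' intervals; the normal-theory CV used for comparability with slice
#' recordings. Undefined (NA) for trains with fewer than 3 spikes.
#'
#' @param train sorted spike times, ms.
#' @return CV (dimensionless), or NA if fewer than 2 ISIs.
#' @export
isiCv <- function(train) {
  x <- diff(train)
  if (length(x) < 2L) return(NA_real_)
  sd(x) / mean(x)
}

#' ISI histogram
#'
#' Counts of inter-spike intervals in half-open bins
#' \eqn{[k\,bw, (k+1)\,bw)}. The counts always sum to the number of ISIs.
#'
#' @param train sorted spike times, ms.
#' @param binWidth bin width, ms (default 1).
#' @return data.frame with binStart, binEnd (ms) and count.
#' @export
isiHistogram <- function(train, binWidth = 1) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  x <- diff(train)
  if (!length(x))
    return(data.frame(binStart = numeric(0), binEnd = numeric(0),
                      count = integer(0)))
  bin <- floor(x / binWidth)
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  data.frame(binStart = (seq_along(counts) - 1L) * binWidth,
             binEnd = seq_along(counts) * binWidth,
             count = counts)
}

#' Spike autocorrelogram
#'
#' Histogram of positive lags between all ordered spike pairs, in half-open
#' bins over (0, maxLag]: bin k holds lags in \eqn{((k-1)bw, k\,bw]}.
#' Zero-lag self-pairs are excluded. Periodic firing shows as peaks at
#' integer multiples of the base interval.
#'
#' @param train sorted spike times, ms.
#' @param binWidth bin width, ms (default 1).
#' @param maxLag largest lag retained, ms (default 100).
#' @return data.frame with lagLow, lagHigh (ms) and count.
#' @export
autocorrelogram <- function(train, binWidth = 1, maxLag = 100) {
  if (binWidth <= 0 || maxLag <= 0) stop("binWidth and maxLag must be > 0")
  nb <- ceiling(maxLag / binWidth)
  counts <- integer(nb)
  n <- length(train)
  for (i in seq_len(n)) {
    jj <- i + 1L
    while (jj <= n) {
      lag <- train[jj] - train[i]
      if (lag > maxLag) break
      if (lag > 0) {
        b <- ceiling(lag / binWidth)
        counts[b] <- counts[b] + 1L
      }
      jj <- jj + 1L
    }
  }
  data.frame(lagLow = (seq_len(nb) - 1L) * binWidth,
             lagHigh = seq_len(nb) * binWidth,
             count = counts)
}

#' Per-neuron and population firing statistics
#'
#' Computes each neuron's mean rate and ISI CV from a simulation, then
#' population summaries (mean, SD, median, first and third quartile) per
#' cell class. Neurons with fewer than \code{minSpikes} spikes have no
#' defined CV; they are excluded from the CV aggregates but kept in the
#' rate aggregates.
#'
#' @param result a \linkS4class{SimResult}.
#' @param minSpikes minimum spikes for a defined CV (default 3).
#' @return list with \code{perNeuron} (data.frame: id, class, nSpikes,
#'   rate, cv) and \code{summary} (data.frame: class, measure, n, mean, sd,
#'   median, q1, q3).
#' @export
populationStats <- function(result, minSpikes = 3L) {
  trains <- spikeTrains(result)
  dur <- result@settings@duration
  nr <- result@network@neurons
  perNeuron <- data.frame(
    id = nr$id, class = nr$class,
    nSpikes = vapply(trains, length, 1L),
    rate = vapply(trains, meanRate, 1, duration = dur),
    cv = vapply(trains, function(tr)
      if (length(tr) >= minSpikes) isiCv(tr) else NA_real_, 1),
    row.names = NULL)
  summarise <- function(x, cls, measure) {
    x <- x[!is.na(x)]
    data.frame(class = cls, measure = measure, n = length(x),
               mean = mean(x), sd = sd(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
  }
  summ <- do.call(rbind, unlist(lapply(unique(perNeuron$class), function(cls) {
    sub <- perNeuron[perNeuron$class == cls, ]
    list(summarise(sub$rate, cls, "rate"), summarise(sub$cv, cls, "cv"))
  }), recursive = FALSE))
  rownames(summ) <- NULL
  list(perNeuron = perNeuron, summary = summ)
}

#' Rate-CV rank correlation
#'
#' Spearman rank correlation between per-neuron mean firing rate and ISI CV
#' (ties get average ranks; the p-value uses the large-sample
#' approximation). In the intact network this association is strongly
#' negative: slowly firing neurons are the irregular ones.
#'
#' @param perNeuron data.frame with columns rate and cv (rows with NA cv
#'   are dropped), e.g. from [populationStats()].
#' @return list with \code{rho} and \code{p}.
#' @export
rateCvCorrelation <- function(perNeuron) {
  ok <- !is.na(perNeuron$cv) & !is.na(perNeuron$rate)
  if (sum(ok) < 3L) stop("need at least 3 neurons with a defined CV")
  ct <- suppressWarnings(cor.test(perNeuron$rate[ok], perNeuron$cv[ok],
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sample Mann-Whitney comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test; U is reported for the
#' first sample against the second.
#'
#' @param a,b numeric samples.
#' @return list with \code{U} and \code{p}.
#' @export
compareDistributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Shapiro-Wilk normality test with large-sample subsampling
#'
#' Shapiro-Wilk on the given sample. The test statistic is defined for
#' 3..5000 observations; larger samples are subsampled to
#' \code{maxN} without replacement under a fixed internal seed
#' (\code{subsampleSeed}) so the result is reproducible.
#'
#' @param x numeric sample (e.g. ISIs).
#' @param maxN subsample cap (default 5000).
#' @param subsampleSeed RNG seed for the subsample draw.
#' @return list with \code{W}, \code{p} and \code{n} (observations used).
#' @export
normalityTest <- function(x, maxN = 5000L, subsampleSeed = 1L) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(x) > maxN)
    x <- .withSeed(subsampleSeed, sample(x, maxN))
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value, n = length(x))
}
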