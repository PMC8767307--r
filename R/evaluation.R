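#' @include AllClasses.R
NULL

#' Construct the test / validation / pre-train / fine-tune splits
#'
#' Reserves a class-balanced test set and validation set (one-to-one ratio
#' of normal to abnormal), leaves the remainder as the pre-train set, and
#' draws a class-balanced fine-tune set from within the pre-train set (the
#' pre-train set is used unlabelled, so the labelled fine-tune subset can
#' live inside it without leaking the held-out sets).  With the default
#' sizes and a cohort of 3,240 recordings this yields a pre-train set of
#' 2,440.  Disjointness of test and validation from everything else is
#' asserted on every call.
#'
#' @param labels character or factor vector of binary labels
#'   (`"normal"`/`"abnormal"` or any two levels).
#' @param testSize,valSize,fineTuneSize total sizes of the reserved sets
#'   (each half per class); defaults 400/400/400.
#' @param seed integer seed.
#' @return list of integer index vectors `test`, `val`, `preTrain`,
#'   `fineTune` (with `fineTune` a subset of `preTrain`).
#' @export
makeSplits <- function(labels, testSize = 400L, valSize = 400L,
                       fineTuneSize = 400L, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("need exactly two classes, got: ", paste(classes, collapse = ", "))
  perClass <- function(sz) {
    if (sz %% 2L != 0L) stop("reserved set sizes must be even for a 1:1 ratio")
    sz %/% 2L
  }
  nt <- perClass(testSize); nv <- perClass(valSize); nf <- perClass(fineTuneSize)
  counts <- table(labels)
  need <- nt + nv + nf
  short <- counts < need
  if (any(short))
    stop("insufficient samples for 1:1 reserved sets: need ", need,
         " per class but have ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  set.seed(seed)
  take <- function(pool, n) {
    sel <- unlist(lapply(classes, function(cl) {
      cand <- pool[labels[pool] == cl]
      sample(cand, n)
    }))
    sort(sel)
  }
  all_idx <- seq_along(labels)
  test <- take(all_idx, nt)
  val <- take(setdiff(all_idx, test), nv)
  preTrain <- sort(setdiff(all_idx, c(test, val)))
  fineTune <- take(preTrain, nf)
  stopifnot(length(intersect(test, val)) == 0L,
            length(intersect(preTrain, c(test, val))) == 0L,
            all(fineTune %in% preTrain))
  list(test = test, val = val, preTrain = preTrain, fineTune = fineTune)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties counted one half.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels; `1`/`TRUE`/`"abnormal"` is the positive
#'   class.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  y <- .asBinary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC needs both classes present (got ", n1, " positive, ",
         n0, " negative)")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.asBinary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (identical(u, c("abnormal", "normal")) || identical(u, "abnormal") ||
      identical(u, "normal"))
    return(as.integer(labels == "abnormal"))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(labels == u[length(u)])
}

#' Bootstrap confidence interval for AUROC
#'
#' Resamples the test set with replacement, recomputes AUROC per
#' replicate, and reports the percentile interval.  Replicates that lose
#' one class entirely are redrawn (and counted); a redraw rate above 10%
#' raises a warning.  The replicate vector is kept so two models evaluated
#' on the same test set can be compared pairwise replicate-by-replicate.
#'
#' @param scores,labels as in [aurocScore()].
#' @param replicates number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed controlling the resampling.
#' @return an [EvalResult-class].
#' @export
bootstrapCI <- function(scores, labels, replicates = 1000L, level = 0.95,
                        seed = 1L) {
  y <- .asBinary(labels)
  point <- aurocScore(scores, y)
  n <- length(scores)
  set.seed(seed)
  vals <- numeric(replicates)
  redraws <- 0L
  for (r in seq_len(replicates)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > 100L * replicates)
        stop("bootstrap cannot find two-class resamples")
    }
    vals[r] <- aurocScore(scores[idx], y[idx])
  }
  if (redraws > 0.1 * replicates)
    warning(sprintf("%d of %d bootstrap replicates were redrawn (single class)",
                    redraws, replicates))
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  new("EvalResult", auroc = point,
      ciLow = min(q[1L], point), ciHigh = max(q[2L], point),
      level = level, bootstrapValues = vals)
}

#' Paired two-tailed t test on replicate AUROCs
#'
#' Classical paired t test on the elementwise differences between two
#' models' replicate AUROC vectors — typically the bootstrap replicates
#' computed on a shared test set with shared resample indices, or the
#' per-replicate-model values of two parallel training arms.
#'
#' @param valuesA,valuesB numeric vectors of equal length sharing a
#'   pairing index.
#' @return list with `t`, `df`, `p`, and the mean difference `meanDiff`.
#' @export
pairedTTest <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("paired vectors must have equal length")
  if (length(valuesA) < 2L) stop("need at least two pairs")
  d <- valuesA - valuesB
  if (stats::sd(d) == 0)
    stop("differences have zero variance; the paired t statistic is undefined")
  ht <- stats::t.test(valuesA, valuesB, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanDiff = mean(d))
}
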