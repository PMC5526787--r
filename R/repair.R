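## Microhomology-guided repair model and frameshift-likelihood test.
##
## At a Cas9 DSB, short exact repeats flanking the cut can anneal and
## resolve the break, deleting one copy plus the intervening sequence.
## Each candidate microhomology pair is scored by a linear model of its
## length, GC fraction and distance to the DSB; a target's frameshift
## (FSM) likelihood is the fraction of total predicted resolution score
## carried by pairs whose deletion length is not divisible by 3. The FSM
## test additionally gates on the per-site sum of predicted likelihoods
## being at least a background-median cutoff (homology-guided repair must
## be likely at all for the frameshift estimate to be meaningful).

#' Enumerate microhomology pairs around a cut
#'
#' Finds every maximal exact repeat with one copy ending at or before the
#' cut and one copy beginning at or after it, both copies within `window`
#' nt of the cut and at least `minLen` nt long. Sub-repeats contained in a
#' longer reported repeat with the same copy alignment are suppressed.
#'
#' @param contextSeq character; sequence around the cut.
#' @param cutIndex 0-based boundary index of the blunt cut within
#'   `contextSeq`.
#' @param minLen minimum homology length in nt (default 2).
#' @param window maximum distance (nt) of either copy from the cut
#'   (default 30).
#' @return data.frame with columns `homology_seq`, `length`, `gc_fraction`,
#'   `dist_upstream` (3' end of the upstream copy to the cut),
#'   `dist_downstream` (cut to 5' start of the downstream copy) and
#'   `deletion_length` (= dist_upstream + dist_downstream + length).
#' @export
enumerateMicrohomologies <- function(contextSeq, cutIndex, minLen = 2L,
                                     window = 30L) {
  s <- toupper(contextSeq)
  L <- nchar(s)
  stopifnot(cutIndex >= 0L, cutIndex <= L)
  ch <- strsplit(s, "")[[1]]
  loU <- max(0L, cutIndex - window)  # upstream copies live in [loU, cut)
  hiD <- min(L, cutIndex + window)   # downstream copies in [cut, hiD)

  res <- list()
  ## u = 0-based start of upstream copy, d = start of downstream copy.
  ## Constraints: upstream copy inside [loU, cutIndex), downstream copy
  ## inside [cutIndex, hiD).
  if (cutIndex == 0L || cutIndex == L)
    return(.emptyMicrohomologyFrame())
  for (u in loU:(cutIndex - 1L)) {
    for (d in cutIndex:(hiD - 1L)) {
      ## maximal extension to the right under the constraints
      len <- 0L
      while (u + len < cutIndex && d + len < hiD &&
             ch[u + len + 1L] == ch[d + len + 1L])
        len <- len + 1L
      if (len < minLen) next
      ## maximality to the left: extendable iff u-1 and d-1 are legal and
      ## match (d-1 must still start at/after the cut and inside windows)
      if (u - 1L >= loU && d - 1L >= cutIndex &&
          ch[u] == ch[d]) next  # covered by the pair starting one left
      seq_ <- substr(s, u + 1L, u + len)
      res[[length(res) + 1L]] <- data.frame(
        homology_seq = seq_,
        length = len,
        gc_fraction = gcFraction(seq_),
        dist_upstream = cutIndex - (u + len),
        dist_downstream = d - cutIndex,
        deletion_length = (d - u),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.emptyMicrohomologyFrame())
  out <- do.call(rbind, res)
  out[order(out$deletion_length, out$dist_upstream, out$homology_seq), ,
      drop = FALSE]
}

.emptyMicrohomologyFrame <- function() {
  data.frame(homology_seq = character(0), length = integer(0),
             gc_fraction = numeric(0), dist_upstream = integer(0),
             dist_downstream = integer(0), deletion_length = integer(0))
}

#' Fit the repair-resolution linear model
#'
#' Ordinary least squares of observed resolution frequency on homology
#' length, GC fraction and distance to the DSB, with intercept.
#'
#' @param resolutionTable data.frame with columns `length`, `gc_fraction`,
#'   `distance`, `frequency` (at least 10 rows).
#' @param distanceMode how a pair's single distance covariate is formed
#'   from its two flank distances at prediction time: "sum" (default) or
#'   "min".
#' @return a [RepairModel-class].
#' @export
fitRepairModel <- function(resolutionTable, distanceMode = c("sum", "min")) {
  distanceMode <- match.arg(distanceMode)
  need <- c("length", "gc_fraction", "distance", "frequency")
  stopifnot(all(need %in% names(resolutionTable)))
  if (nrow(resolutionTable) < 10L)
    stop("at least 10 resolution observations are required")
  X <- resolutionTable[, c("length", "gc_fraction", "distance")]
  constant <- vapply(X, function(col) length(unique(col)) < 2L, logical(1))
  if (any(constant))
    stop("rank-deficient design: constant predictor(s) ",
         paste(names(X)[constant], collapse = ", "))
  fit <- lm(frequency ~ length + gc_fraction + distance,
            data = resolutionTable)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design: collinear predictor(s) ",
         paste(bad, collapse = ", "))
  }
  co <- coef(fit)
  names(co) <- c("intercept", "length", "gc_fraction", "distance")
  new("RepairModel", coefficients = co,
      fitDiagnostics = list(
        sigma = summary(fit)$sigma,
        r_squared = summary(fit)$r.squared,
        residual_quartiles = unname(quantile(stats::residuals(fit),
                                             c(0.25, 0.5, 0.75)))),
      hejCutoff = NA_real_, distanceMode = distanceMode)
}

#' Predict resolution likelihood for microhomology pairs
#'
#' Linear combination of (length, gc_fraction, distance) plus intercept,
#' clamped at zero. The distance covariate is the sum (or, when the model
#' was fitted with `distanceMode = "min"`, the minimum) of the pair's two
#' flank distances.
#'
#' @param model a fitted [RepairModel-class].
#' @param pairs data.frame from [enumerateMicrohomologies()].
#' @return numeric vector of non-negative likelihood scores.
#' @export
predictResolution <- function(model, pairs) {
  if (nrow(pairs) == 0L) return(numeric(0))
  d <- if (model@distanceMode == "min")
    pmin(pairs$dist_upstream, pairs$dist_downstream)
  else pairs$dist_upstream + pairs$dist_downstream
  co <- model@coefficients
  raw <- co[["intercept"]] + co[["length"]] * pairs$length +
    co[["gc_fraction"]] * pairs$gc_fraction + co[["distance"]] * d
  pmax(raw, 0)
}

#' Frameshift-likelihood assessment at a target
#'
#' The FSM likelihood is the fraction of total predicted resolution score
#' carried by microhomology pairs whose deletion length is not divisible
#' by 3. The target passes the FSM test iff the likelihood strictly
#' exceeds `fsmThreshold` and the unnormalized likelihood sum meets the
#' model's HEJ cutoff (when one is set). When no pair scores above zero
#' the likelihood is undefined (NA) and the test fails.
#'
#' @param model a [RepairModel-class].
#' @param contextSeq sequence around the cut.
#' @param cutIndex 0-based cut boundary within `contextSeq`.
#' @param fsmThreshold strict lower bound on the FSM likelihood
#'   (default 0.66, i.e. pass requires > 66% chance of a frameshift).
#' @param minLen,window passed to [enumerateMicrohomologies()].
#' @return list with `fsm_likelihood`, `hej_sum`, `passes_fsm_test`.
#' @export
assessFsm <- function(model, contextSeq, cutIndex, fsmThreshold = 0.66,
                      minLen = 2L, window = 30L) {
  pairs <- enumerateMicrohomologies(contextSeq, cutIndex, minLen, window)
  scores <- predictResolution(model, pairs)
  hejSum <- sum(scores)
  if (hejSum <= 0) {
    return(list(fsm_likelihood = NA_real_, hej_sum = hejSum,
                passes_fsm_test = FALSE))
  }
  fsm <- sum(scores[pairs$deletion_length %% 3L != 0L]) / hejSum
  gate <- if (is.na(model@hejCutoff)) TRUE else hejSum >= model@hejCutoff
  list(fsm_likelihood = fsm, hej_sum = hejSum,
       passes_fsm_test = (fsm > fsmThreshold) && gate)
}

#' Set the HEJ-applicability cutoff from a background site collection
#'
#' The cutoff is the median of per-site predicted-likelihood sums over a
#' background collection of coding-sequence Cas9 sites; targets whose own
#' sum falls below it fail the FSM test regardless of their frameshift
#' fraction.
#'
#' @param model a [RepairModel-class].
#' @param backgroundContexts character vector of site context sequences.
#' @param backgroundCuts integer vector of 0-based cut boundaries, one per
#'   context (default: midpoint of each).
#' @param minLen,window passed to [enumerateMicrohomologies()].
#' @return the model with `hejCutoff` set.
#' @export
computeHejCutoff <- function(model, backgroundContexts,
                             backgroundCuts = NULL, minLen = 2L,
                             window = 30L) {
  if (!length(backgroundContexts))
    stop("background site collection is empty")
  if (is.null(backgroundCuts))
    backgroundCuts <- nchar(backgroundContexts) %/% 2L
  sums <- mapply(function(ctx, cut) {
    pairs <- enumerateMicrohomologies(ctx, cut, minLen, window)
    sum(predictResolution(model, pairs))
  }, backgroundContexts, backgroundCuts)
  model@hejCutoff <- median(as.numeric(sums))
  model
}
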