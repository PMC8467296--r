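#' Find the coldest contiguous k-day interval of an ambient series
#'
#' Scans every candidate start (the first timestamp plus whole-day offsets)
#' and returns the contiguous `k_days`-day window minimising the mean
#' ambient temperature over the observations it contains; ties are broken by
#' the earliest start.
#'
#' @param ambient data frame with columns `timestamp` (`POSIXct`, strictly
#'   increasing) and `temp_c`.
#' @param k_days window length in days.
#' @return a length-2 `POSIXct` vector `c(start, end)`; the interval is
#'   `[start, end)`.
#' @export
coldest_interval <- function(ambient, k_days = 5) {
  ts <- as.numeric(ambient$timestamp)
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("ambient timestamps must be strictly increasing", call. = FALSE)
  }
  day <- 86400
  span_days <- floor((ts[length(ts)] - ts[1]) / day) + 1
  if (span_days < k_days) {
    stop(sprintf("series spans %d whole day(s); need at least %d",
                 span_days, k_days), call. = FALSE)
  }
  starts <- ts[1] + (0:(span_days - k_days)) * day
  means <- vapply(starts, function(s) {
    sel <- ts >= s & ts < s + k_days * day
    if (!any(sel)) Inf else mean(ambient$temp_c[sel])
  }, numeric(1))
  best <- which.min(means)  # which.min takes the earliest tie
  out <- as.POSIXct(c(starts[best], starts[best] + k_days * day),
                    origin = "1970-01-01", tz = "UTC")
  out
}

#' Trapezoidal area under a temperature series over an interval
#'
#' Integrates the piecewise-linear interpolant of temperature against time
#' restricted to `[start, end)`, with time measured in hours, so the result
#' is in degree-Celsius-hours. When samples straddle an interval boundary
#' the series is linearly interpolated at the boundary; when the series
#' starts or ends inside the interval the integral is over the covered part.
#'
#' @param series data frame with columns `timestamp` (`POSIXct`) and
#'   `temp_c`.
#' @param interval length-2 `POSIXct` (or numeric seconds) vector, e.g. from
#'   [coldest_interval()].
#' @return AUC in degree-Celsius hours.
#' @export
temp_auc <- function(series, interval) {
  ts <- as.numeric(series$timestamp)
  y <- series$temp_c
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("series timestamps must be strictly increasing", call. = FALSE)
  }
  t0 <- as.numeric(interval[1])
  t1 <- as.numeric(interval[2])
  inside <- ts >= t0 & ts <= t1
  if (sum(inside) < 2) {
    stop("need at least 2 observations inside the interval", call. = FALSE)
  }
  tt <- ts[inside]
  yy <- y[inside]
  if (tt[1] > t0 && any(ts < t0)) {
    y0 <- stats::approx(ts, y, xout = t0)$y
    tt <- c(t0, tt)
    yy <- c(y0, yy)
  }
  if (tt[length(tt)] < t1 && any(ts > t1)) {
    y1 <- stats::approx(ts, y, xout = t1)$y
    tt <- c(tt, t1)
    yy <- c(yy, y1)
  }
  th <- tt / 3600  # hours
  sum(diff(th) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Per-animal AUC phenotypes over an interval
#'
#' @param readings long data frame with columns `animal_id`, `timestamp`,
#'   `temp_c`.
#' @param interval length-2 `POSIXct` vector (e.g. the coldest five days).
#' @return data frame with columns `animal_id`, `auc`.
#' @export
compute_phenotypes <- function(readings, interval) {
  ids <- unique(readings$animal_id)
  auc <- vapply(ids, function(id) {
    temp_auc(readings[readings$animal_id == id, , drop = FALSE], interval)
  }, numeric(1))
  data.frame(animal_id = ids, auc = auc, stringsAsFactors = FALSE,
             row.names = NULL)
}

# enumerate all per-breed count vectors summing to `total` with caps
.compositions <- function(total, caps) {
  if (length(caps) == 1L) {
    if (total <= caps) return(matrix(total, nrow = 1)) else
      return(matrix(numeric(0), ncol = 1))
  }
  out <- list()
  for (k in 0:min(total, caps[1])) {
    rest <- .compositions(total - k, caps[-1])
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(k, rest)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = length(caps)))
  do.call(rbind, out)
}

#' Select breed-balanced extreme phenotype groups
#'
#' Splits animals into a high-AUC ("tolerant") and a low-AUC ("sensitive")
#' group of `per_group` animals each, subject to the balance constraint that
#' each breed's count differs by at most one between the groups. The
#' optimiser searches all feasible per-breed group compositions, filling
#' each composition with that breed's top-AUC (tolerant) and bottom-AUC
#' (sensitive) animals, and keeps the composition maximising the difference
#' in group AUC sums — which is exactly the optimum over all balanced group
#' pairs. Fully deterministic: AUC ties are broken by `animal_id`, and
#' objective ties by enumeration order over compositions (breeds in sorted
#' order).
#'
#' @param phenotypes data frame with columns `animal_id`, `auc`, `breed`.
#' @param per_group animals per group.
#' @return a data frame (`sample_id`, `group`, `breed`) with group labels
#'   `"tolerant"` and `"sensitive"`.
#' @export
select_extreme_groups <- function(phenotypes, per_group = 6) {
  req <- c("animal_id", "auc", "breed")
  stopifnot(all(req %in% names(phenotypes)))
  ph <- phenotypes[req]
  if (nrow(ph) < 2 * per_group) {
    stop(sprintf("need at least %d animals, got %d", 2 * per_group, nrow(ph)),
         call. = FALSE)
  }
  if (any(!is.finite(ph$auc))) stop("non-finite AUC values", call. = FALSE)
  breeds <- sort(unique(as.character(ph$breed)))
  # per breed, ids ordered by descending AUC (ties by animal_id)
  by_breed <- lapply(breeds, function(b) {
    sub <- ph[ph$breed == b, , drop = FALSE]
    sub[order(-sub$auc, sub$animal_id), , drop = FALSE]
  })
  names(by_breed) <- breeds
  caps <- vapply(by_breed, nrow, integer(1))
  comp_t <- .compositions(per_group, caps)
  if (!nrow(comp_t)) stop("breed balance unachievable", call. = FALSE)
  top_sum <- function(b, k) if (k == 0) 0 else sum(by_breed[[b]]$auc[seq_len(k)])
  bot_sum <- function(b, k) {
    if (k == 0) return(0)
    n <- caps[[b]]
    sum(by_breed[[b]]$auc[seq(n - k + 1, n)])
  }
  best <- NULL
  best_obj <- -Inf
  for (i in seq_len(nrow(comp_t))) {
    ct <- comp_t[i, ]
    # feasible sensitive compositions near ct
    comp_s <- .compositions(per_group, pmin(caps - ct, ct + 1))
    if (!nrow(comp_s)) next
    ok <- apply(comp_s, 1, function(cs) all(abs(cs - ct) <= 1))
    comp_s <- comp_s[ok, , drop = FALSE]
    for (j in seq_len(nrow(comp_s))) {
      cs <- comp_s[j, ]
      obj <- sum(vapply(seq_along(breeds), function(bi) {
        top_sum(bi, ct[bi]) - bot_sum(bi, cs[bi])
      }, numeric(1)))
      if (obj > best_obj + 1e-12) {
        best_obj <- obj
        best <- list(ct = ct, cs = cs)
      }
    }
  }
  if (is.null(best)) stop("breed balance unachievable", call. = FALSE)
  tol <- unlist(lapply(seq_along(breeds), function(bi) {
    utils::head(by_breed[[bi]]$animal_id, best$ct[bi])
  }))
  sen <- unlist(lapply(seq_along(breeds), function(bi) {
    utils::tail(by_breed[[bi]]$animal_id, best$cs[bi])
  }))
  out <- data.frame(
    sample_id = c(tol, sen),
    group = rep(c("tolerant", "sensitive"), c(length(tol), length(sen))),
    stringsAsFactors = FALSE
  )
  out$breed <- ph$breed[match(out$sample_id, ph$animal_id)]
  if (!all(ph$auc == ph$auc[1])) {
    mt <- mean(ph$auc[match(tol, ph$animal_id)])
    ms <- mean(ph$auc[match(sen, ph$animal_id)])
    if (!(mt > ms)) {
      stop("internal error: tolerant group does not exceed sensitive group",
           call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}
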