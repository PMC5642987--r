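#' Crossing resolution of two partition lines
#'
#' Two single-layer partitions with coefficients \eqn{(\hat{A}_1,
#' \hat{P}_1)} and \eqn{(\hat{A}_2, \hat{P}_2)} have equal modularity at
#' \deqn{\gamma^* = (\hat{A}_1 - \hat{A}_2) / (\hat{P}_1 - \hat{P}_2).}
#' Equal slopes mean the lines never cross (or coincide).
#'
#' @param rec1,rec2 single coefficient records (one-row data frames or
#'   lists with `a_hat`, `p_hat`).
#' @return the crossing value of gamma, or the character sentinel
#'   `"parallel"` when `p_hat` values are equal.
#' @export
intersection_gamma <- function(rec1, rec2) {
  if (rec1$p_hat == rec2$p_hat) return("parallel")
  (rec1$a_hat - rec2$a_hat) / (rec1$p_hat - rec2$p_hat)
}

#' Prune a partition ensemble to its gamma-domains of optimality
#'
#' Builds the upper envelope of the partition lines
#' \eqn{Q_\sigma(\gamma) = \hat{A}_\sigma - \gamma \hat{P}_\sigma} over
#' `[gamma_start, gamma_end)` by forward iteration: the optimal line at
#' `gamma_start` is found directly (ties broken by smaller `p_hat`, then
#' lower id), then the algorithm repeatedly finds the smallest crossing
#' beyond the current transition point and switches to the crossing line.
#' When several lines pass through the same transition point, the one with
#' smallest `p_hat` (then lowest id) takes over. Partitions whose line is
#' nowhere maximal are pruned; the survivors are the admissible subset,
#' each with a simply connected half-open domain
#' \eqn{[\gamma_p, \gamma_{p+1})}.
#'
#' Records with identical `(a_hat, p_hat)` are collapsed to the lowest-id
#' representative and reported in `co_optimal`.
#'
#' @param records data frame of single-layer coefficient records
#'   (`partition_id`, `a_hat`, `p_hat`; `c_hat`, if present, must be 0).
#' @param gamma_start left end of the analysis range (default 0).
#' @param gamma_end right end (default `Inf`).
#' @param tol absolute tolerance on gamma for comparing crossings
#'   (default 1e-12); domains narrower than `tol` are dropped.
#' @return an object of class `champ_envelope1d`: list with `domains`
#'   (data frame `partition_id`, `gamma_lo`, `gamma_hi`, `a_hat`, `p_hat`,
#'   `n_communities`, `n_communities_min5` where available), `gamma_start`,
#'   `gamma_end`, `input_count`, `pruned_count`, `co_optimal` (list mapping
#'   representative id to duplicate ids).
#' @examples
#' recs <- data.frame(partition_id = 1:3,
#'                    a_hat = c(6, 4, 0), p_hat = c(6, 3, 2))
#' champ_prune_1d(recs)$domains
#' @export
champ_prune_1d <- function(records, gamma_start = 0, gamma_end = Inf,
                           tol = 1e-12) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty record list")
  if (!all(is.finite(records$a_hat)) || !all(is.finite(records$p_hat)))
    stop("records with non-finite coefficients")
  if (!is.null(records$c_hat) && any(records$c_hat != 0))
    stop("champ_prune_1d requires single-layer records (c_hat = 0)")
  if (gamma_start >= gamma_end) stop("gamma_start must be < gamma_end")
  if (is.null(records$partition_id))
    records$partition_id <- seq_len(nrow(records))
  records <- records[order(records$partition_id), , drop = FALSE]

  # collapse exact duplicates in (a_hat, p_hat): co-optimal everywhere
  key <- paste(records$a_hat, records$p_hat)
  first <- !duplicated(key)
  co_optimal <- list()
  if (any(!first)) {
    for (k in unique(key[!first])) {
      grp <- records$partition_id[key == k]
      co_optimal[[as.character(grp[1])]] <- grp[-1]
    }
  }
  recs <- records[first, , drop = FALSE]

  a <- recs$a_hat; p <- recs$p_hat; id <- recs$partition_id
  nrec <- length(a)
  # start: argmax Q(gamma_start); ties by smaller p_hat then lower id
  q0 <- a - gamma_start * p
  ord0 <- order(-q0, p, id)
  cur <- ord0[1]
  gamma_p <- gamma_start
  dom_idx <- integer(0); dom_lo <- numeric(0); dom_hi <- numeric(0)
  repeat {
    steeper <- which(p < p[cur] - 0)       # only these can overtake later
    if (length(steeper)) {
      g_cross <- (a[cur] - a[steeper]) / (p[cur] - p[steeper])
      ok <- g_cross > gamma_p + tol & g_cross < gamma_end
      steeper <- steeper[ok]; g_cross <- g_cross[ok]
    } else g_cross <- numeric(0)
    if (!length(g_cross)) {
      dom_idx <- c(dom_idx, cur); dom_lo <- c(dom_lo, gamma_p)
      dom_hi <- c(dom_hi, gamma_end)
      break
    }
    g_next <- min(g_cross)
    at_next <- steeper[g_cross <= g_next + tol]
    if (length(at_next) > 1L) {
      o <- order(p[at_next], id[at_next])   # smallest p_hat, then lowest id
      at_next <- at_next[o]
    }
    nxt <- at_next[1]
    if (g_next - gamma_p >= tol) {
      dom_idx <- c(dom_idx, cur); dom_lo <- c(dom_lo, gamma_p)
      dom_hi <- c(dom_hi, g_next)
    }
    cur <- nxt
    gamma_p <- g_next
  }
  domains <- recs[dom_idx, , drop = FALSE]
  domains$gamma_lo <- dom_lo
  domains$gamma_hi <- dom_hi
  keep_cols <- c("partition_id", "gamma_lo", "gamma_hi", "a_hat", "p_hat",
                 intersect(c("n_communities", "n_communities_min5"),
                           names(domains)))
  domains <- domains[, keep_cols]
  rownames(domains) <- NULL
  structure(list(domains = domains, gamma_start = gamma_start,
                 gamma_end = gamma_end,
                 input_count = nrow(records),
                 pruned_count = nrow(records) - nrow(domains),
                 co_optimal = co_optimal),
            class = "champ_envelope1d")
}

#' @export
print.champ_envelope1d <- function(x, ...) {
  cat(sprintf(paste0("champ_envelope1d: %d admissible of %d input ",
                     "partitions on [%g, %g)\n"),
              nrow(x$domains), x$input_count, x$gamma_start, x$gamma_end))
  print(x$domains, ...)
  invisible(x)
}

#' Evaluate the piecewise-linear optimal-modularity envelope
#'
#' Returns, for each `gamma`, the value of the unique covering domain's
#' line and its partition id; by the half-open convention a transition
#' point belongs to the incoming (larger-gamma) domain.
#'
#' @param env a `champ_envelope1d`.
#' @param gamma numeric vector of resolution values inside
#'   `[gamma_start, gamma_end)`.
#' @return data frame with columns `gamma`, `q`, `partition_id`.
#' @export
envelope_value <- function(env, gamma) {
  stopifnot(inherits(env, "champ_envelope1d"))
  if (any(gamma < env$gamma_start | gamma >= env$gamma_end))
    stop("gamma outside envelope range")
  d <- env$domains
  idx <- findInterval(gamma, d$gamma_lo)   # domains tile the range
  data.frame(gamma = gamma,
             q = d$a_hat[idx] - gamma * d$p_hat[idx],
             partition_id = d$partition_id[idx])
}
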