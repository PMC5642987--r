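# Convex polygon helpers for the (gamma, omega) parameter plane.
# Polygons are matrices with columns (gamma, omega), vertices in CCW order,
# not closed (first vertex not repeated).

polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# Sutherland-Hodgman clip of a convex polygon by the halfplane
# c0 + cg*gamma + cw*omega >= 0. CCW orientation is preserved.
clip_halfplane <- function(poly, cg, cw, c0, tol = 1e-12) {
  if (is.null(poly) || nrow(poly) == 0L) return(NULL)
  f <- c0 + cg * poly[, 1] + cw * poly[, 2]
  if (all(f >= -tol)) return(poly)
  if (all(f < -tol)) return(NULL)
  nv <- nrow(poly)
  out <- matrix(0, nrow = 2L * nv, ncol = 2L)
  k <- 0L
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    fi <- f[i]; fj <- f[j]
    if (fi >= -tol) { k <- k + 1L; out[k, ] <- poly[i, ] }
    if ((fi > tol && fj < -tol) || (fi < -tol && fj > tol)) {
      t <- fi / (fi - fj)
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k < 3L) return(NULL)
  out <- out[seq_len(k), , drop = FALSE]
  dedupe_vertices(out)
}

# drop consecutive vertices closer than tol (also first vs last)
dedupe_vertices <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 0L) return(NULL)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i] && sqrt(sum((poly[i, ] - poly[j, ])^2)) < tol && n - sum(!keep) > 1L)
      keep[j] <- FALSE
  }
  out <- poly[keep, , drop = FALSE]
  if (nrow(out) < 3L) return(NULL)
  out
}

box_polygon <- function(gamma_range, omega_range) {
  matrix(c(gamma_range[1], omega_range[1],
           gamma_range[2], omega_range[1],
           gamma_range[2], omega_range[2],
           gamma_range[1], omega_range[2]),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("gamma", "omega")))
}

# intersection of two convex CCW polygons (possibly degenerate)
convex_intersection <- function(pa, pb, tol = 1e-9) {
  res <- pa
  nb <- nrow(pb)
  for (i in seq_len(nb)) {
    j <- if (i == nb) 1L else i + 1L
    # halfplane left of directed edge pb[i] -> pb[j]
    dx <- pb[j, 1] - pb[i, 1]; dy <- pb[j, 2] - pb[i, 2]
    # cross((dx,dy), (x,y)-pb[i]) >= 0  =>  -dy*x + dx*y + (dy*xi - dx*yi) >= 0
    res0 <- res
    if (is.null(res)) break
    f <- -dy * res[, 1] + dx * res[, 2] + (dy * pb[i, 1] - dx * pb[i, 2])
    if (all(f >= -tol)) next
    if (all(f < -tol)) { res <- NULL; break }
    # inline S-H keeping points within tol of the line (degenerate OK)
    nv <- nrow(res0); outm <- matrix(0, 2L * nv, 2L); k <- 0L
    for (ii in seq_len(nv)) {
      jj <- if (ii == nv) 1L else ii + 1L
      fi <- f[ii]; fj <- f[jj]
      if (fi >= -tol) { k <- k + 1L; outm[k, ] <- res0[ii, ] }
      if ((fi > tol && fj < -tol) || (fi < -tol && fj > tol)) {
        t <- fi / (fi - fj)
        k <- k + 1L
        outm[k, ] <- res0[ii, ] + t * (res0[jj, ] - res0[ii, ])
      }
    }
    res <- if (k == 0L) NULL else outm[seq_len(k), , drop = FALSE]
  }
  res
}

#' Prune a multilayer partition ensemble to (gamma, omega) domains
#'
#' Each partition's plane \eqn{Q_\sigma(\gamma,\omega) = \hat{A}_\sigma -
#' \gamma\hat{P}_\sigma + \omega\hat{C}_\sigma} defines the halfspace above
#' it in \eqn{(\gamma, \omega, Q)}; the intersection of these halfspaces has
#' as lower boundary the pointwise-maximum modularity surface, and its
#' projection tiles the parameter box with convex polygons. The domain of
#' each plane is computed by clipping the box with the halfplanes
#' \eqn{Q_\sigma \ge Q_\tau} against every other plane; planes whose domain
#' is empty (area below `area_tol`) are pruned. Planes never optimal inside
#' the box but optimal somewhere in the enlarged quadrant
#' `[0, 10*gamma_hi] x [0, 10*omega_hi]` are reported in `out_of_box`.
#'
#' Records with identical `(a_hat, p_hat, c_hat)` are collapsed to the
#' lowest-id representative (reported in `co_optimal`).
#'
#' @param records data frame of coefficient records (`partition_id`,
#'   `a_hat`, `p_hat`, `c_hat`).
#' @param gamma_range,omega_range numeric length-2 vectors delimiting the
#'   parameter box.
#' @param area_tol domains with area below this are dropped (default 1e-9).
#' @param find_out_of_box logical; search the enlarged box for admissible
#'   partitions outside the user box (default TRUE).
#' @return object of class `champ_domains2d`: list with `domains` (list of
#'   per-domain lists: `partition_id`, `vertices` CCW matrix, `area`,
#'   `record`), `adjacency` (data frame `id1`, `id2`, `border_length`),
#'   `out_of_box` (integer ids), `box`, `input_count`, `pruned_count`,
#'   `co_optimal`.
#' @examples
#' recs <- data.frame(partition_id = 1:3, a_hat = c(6, 4, 0),
#'                    p_hat = c(6, 3, 2), c_hat = c(0, 1, 3))
#' m <- champ_prune_2d(recs, c(0, 2), c(0, 2))
#' vapply(m$domains, function(d) d$area, numeric(1))
#' @export
champ_prune_2d <- function(records, gamma_range, omega_range,
                           area_tol = 1e-9, find_out_of_box = TRUE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty record list")
  if (is.null(records$c_hat)) records$c_hat <- 0
  if (!all(is.finite(records$a_hat)) || !all(is.finite(records$p_hat)) ||
      !all(is.finite(records$c_hat)))
    stop("records with non-finite coefficients")
  if (length(gamma_range) != 2L || length(omega_range) != 2L ||
      gamma_range[1] >= gamma_range[2] || omega_range[1] >= omega_range[2])
    stop("degenerate parameter box")
  if (is.null(records$partition_id))
    records$partition_id <- seq_len(nrow(records))
  records <- records[order(records$partition_id), , drop = FALSE]
  key <- paste(records$a_hat, records$p_hat, records$c_hat)
  first <- !duplicated(key)
  co_optimal <- list()
  if (any(!first)) {
    for (k in unique(key[!first])) {
      grp <- records$partition_id[key == k]
      co_optimal[[as.character(grp[1])]] <- grp[-1]
    }
  }
  recs <- records[first, , drop = FALSE]

  domains_in <- prune_box(recs, gamma_range, omega_range, area_tol)
  in_ids <- vapply(domains_in, function(d) d$partition_id, numeric(1))

  out_of_box <- integer(0)
  if (find_out_of_box && nrow(recs) > length(domains_in)) {
    big <- prune_box(recs, c(0, 10 * gamma_range[2]),
                     c(0, 10 * omega_range[2]), area_tol)
    big_ids <- vapply(big, function(d) d$partition_id, numeric(1))
    out_of_box <- as.integer(setdiff(big_ids, in_ids))
  }

  map <- structure(list(domains = domains_in,
                        adjacency = NULL,
                        out_of_box = out_of_box,
                        box = list(gamma = gamma_range, omega = omega_range),
                        input_count = nrow(records),
                        pruned_count = nrow(records) - length(domains_in),
                        co_optimal = co_optimal),
                   class = "champ_domains2d")
  map$adjacency <- domain_adjacency(map)
  map
}

# core clipping loop over one box
prune_box <- function(recs, gamma_range, omega_range, area_tol) {
  a <- recs$a_hat; p <- recs$p_hat; cc <- recs$c_hat
  n <- nrow(recs)
  box <- box_polygon(gamma_range, omega_range)
  domains <- list()
  for (k in seq_len(n)) {
    poly <- box
    for (j in seq_len(n)) {
      if (j == k) next
      # Q_k - Q_j >= 0
      poly <- clip_halfplane(poly, cg = -(p[k] - p[j]), cw = cc[k] - cc[j],
                             c0 = a[k] - a[j])
      if (is.null(poly)) break
    }
    if (is.null(poly)) next
    ar <- polygon_area(poly)
    if (ar < area_tol) next
    colnames(poly) <- c("gamma", "omega")
    domains[[length(domains) + 1L]] <-
      list(partition_id = recs$partition_id[k], vertices = poly, area = ar,
           record = recs[k, , drop = FALSE])
  }
  domains
}

#' @export
print.champ_domains2d <- function(x, ...) {
  cat(sprintf(paste0("champ_domains2d: %d admissible of %d input ",
                     "partitions in [%g, %g] x [%g, %g]",
                     " (%d admissible only outside the box)\n"),
              length(x$domains), x$input_count,
              x$box$gamma[1], x$box$gamma[2],
              x$box$omega[1], x$box$omega[2], length(x$out_of_box)))
  invisible(x)
}

#' Border adjacency between 2-D domains of optimality
#'
#' Two domains are adjacent when their polygons share a border segment of
#' positive length (domains meeting only at a point are not adjacent). The
#' returned border lengths feed the border-weighted neighbor-averaged AMI.
#'
#' @param map a `champ_domains2d`.
#' @param length_tol minimum shared-segment length to count as adjacency.
#' @return data frame with columns `id1`, `id2`, `border_length`
#'   (`id1 < id2`, each adjacent pair once).
#' @export
domain_adjacency <- function(map, length_tol = 1e-6) {
  stopifnot(inherits(map, "champ_domains2d"))
  doms <- map$domains
  nd <- length(doms)
  out <- list()
  if (nd >= 2L) {
    for (i in seq_len(nd - 1L)) {
      for (j in seq.int(i + 1L, nd)) {
        inter <- convex_intersection(doms[[i]]$vertices, doms[[j]]$vertices,
                                     tol = 1e-7)
        if (is.null(inter) || nrow(inter) < 2L) next
        dmat <- as.matrix(dist(inter))
        len <- max(dmat)
        if (len > length_tol) {
          out[[length(out) + 1L]] <-
            data.frame(id1 = doms[[i]]$partition_id,
                       id2 = doms[[j]]$partition_id,
                       border_length = len)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(id1 = integer(0), id2 = integer(0),
                      border_length = numeric(0)))
  do.call(rbind, out)
}

#' Look up the optimal partition at parameter points
#'
#' Point-in-polygon query over a 2-D domain map; on a border the domain
#' with the smaller partition id wins (deterministic tie rule).
#'
#' @param map a `champ_domains2d`.
#' @param gamma,omega numeric vectors (recycled to common length) of points
#'   inside the parameter box.
#' @return integer vector of partition ids.
#' @export
assign_point <- function(map, gamma, omega) {
  stopifnot(inherits(map, "champ_domains2d"))
  np <- max(length(gamma), length(omega))
  gamma <- rep_len(gamma, np); omega <- rep_len(omega, np)
  bx <- map$box
  if (any(gamma < bx$gamma[1] - 1e-12 | gamma > bx$gamma[2] + 1e-12 |
          omega < bx$omega[1] - 1e-12 | omega > bx$omega[2] + 1e-12))
    stop("point outside box")
  doms <- map$domains
  ids <- vapply(doms, function(d) d$partition_id, numeric(1))
  ord <- order(ids)
  res <- rep(NA_integer_, np)
  todo <- rep(TRUE, np)
  for (d in doms[ord]) {
    if (!any(todo)) break
    poly <- d$vertices
    nv <- nrow(poly)
    inside <- todo
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      dx <- poly[j, 1] - poly[i, 1]; dy <- poly[j, 2] - poly[i, 2]
      f <- dx * (omega - poly[i, 2]) - dy * (gamma - poly[i, 1])
      inside <- inside & f >= -1e-9
      if (!any(inside)) break
    }
    res[inside] <- as.integer(d$partition_id)
    todo <- todo & !inside
  }
  if (any(todo)) {
    # numerical fallback: pick max-Q plane among admissible domains
    recs <- do.call(rbind, lapply(doms, function(d) d$record))
    for (ii in which(todo)) {
      q <- recs$a_hat - gamma[ii] * recs$p_hat + omega[ii] * recs$c_hat
      res[ii] <- as.integer(recs$partition_id[which.max(q)])
    }
  }
  res
}
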