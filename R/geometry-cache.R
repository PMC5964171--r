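# Bulk MTU geometry evaluation.
#
# The public mtu_length()/moment_arm() operate one MTU at a time, which is
# what users need but too slow inside the forward-dynamics right-hand side
# and the per-timestep static optimization (dozens of MTUs times finite
# differences). The cache below stacks every via point of every MTU into
# one matrix per owning segment so a single pose evaluation is a handful of
# matrix products.

# Build the cache: per segment, a 3 x n matrix of local via points and the
# global column index; per MTU, the ordered global indices of its points.
mtu_geometry_cache <- function(model) {
  labels <- names(model$mtus)
  seg_pts <- list()
  seg_idx <- list()
  mtu_idx <- vector("list", length(labels))
  names(mtu_idx) <- labels
  counter <- 0L
  for (lb in labels) {
    via <- model$mtus[[lb]]$path$via
    idx <- integer(nrow(via))
    for (i in seq_len(nrow(via))) {
      counter <- counter + 1L
      sg <- via$segment[i]
      seg_pts[[sg]] <- cbind(seg_pts[[sg]], c(via$x[i], via$y[i], via$z[i]))
      seg_idx[[sg]] <- c(seg_idx[[sg]], counter)
      idx[i] <- counter
    }
    mtu_idx[[lb]] <- idx
  }
  spanned <- lapply(model$mtus, function(m) m$path$spanned)
  list(seg_pts = seg_pts, seg_idx = seg_idx, mtu_idx = mtu_idx,
       n_points = counter, labels = labels, spanned = spanned)
}

# All MTU lengths at a pose (named vector), one transform pass per segment.
all_mtu_lengths <- function(model, q, cache) {
  Ts <- segment_transforms(model, q)
  world <- matrix(0, 3, cache$n_points)
  for (sg in names(cache$seg_pts)) {
    T <- Ts[[sg]]
    world[, cache$seg_idx[[sg]]] <-
      T[1:3, 1:3] %*% cache$seg_pts[[sg]] + T[1:3, 4]
  }
  vapply(cache$labels, function(lb) {
    pts <- world[, cache$mtu_idx[[lb]], drop = FALSE]
    sum(sqrt(colSums((pts[, -1, drop = FALSE] -
                        pts[, -ncol(pts), drop = FALSE])^2)))
  }, numeric(1))
}

# Parameter table for vectorized rigid-tendon force evaluation.
mtu_param_matrix <- function(model) {
  labels <- names(model$mtus)
  out <- do.call(rbind, lapply(labels, function(lb) {
    p <- model$mtus[[lb]]$params
    c(f_max = p$f_max, l_opt = p$l_opt, l_ts = p$l_ts,
      w = p$l_opt * sin(deg2rad(p$pennation0)), v_max = p$v_max)
  }))
  rownames(out) <- labels
  out
}

# Rigid-tendon tendon-line forces of all MTUs at once (passive omitted;
# slack tendons contribute zero). `a`, `L`, `V` are vectors over MTUs.
rigid_forces_bulk <- function(par, curves, a, L, V) {
  proj <- L - par[, "l_ts"]
  taut <- proj > par[, "l_ts"] * 1e-9 & proj > 0
  lf <- sqrt(pmax(proj, 0)^2 + par[, "w"]^2)
  lf <- pmax(lf, 1e-12)
  cosa <- pmax(proj, 0) / lf
  lnorm <- lf / par[, "l_opt"]
  vnorm <- (V * cosa) / (par[, "v_max"] * par[, "l_opt"])
  F <- par[, "f_max"] * a * curves$active_fl(lnorm) * curves$fv(vnorm) * cosa
  F[!taut] <- 0
  pmax(F, 0)
}

# Moment arms of all MTUs about the requested coordinates by central
# differences of the bulk lengths (MTUs x coords).
all_moment_arms <- function(model, q, coords, cache, step = 1e-5) {
  q <- complete_pose(model, q)
  R <- matrix(0, length(cache$labels), length(coords),
              dimnames = list(cache$labels, coords))
  for (cc in coords) {
    if (!any(vapply(cache$spanned, function(s) cc %in% s, logical(1))))
      next
    qp <- qm <- q
    qp[cc] <- qp[cc] + step
    qm[cc] <- qm[cc] - step
    dL <- (all_mtu_lengths(model, qp, cache) -
             all_mtu_lengths(model, qm, cache)) / (2 * step)
    # zero out MTUs that do not span the coordinate (exact invariance)
    dL[!vapply(cache$spanned, function(s) cc %in% s, logical(1))] <- 0
    R[, cc] <- -dL
  }
  R
}
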