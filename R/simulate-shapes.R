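#' Template EDJ-like landmark configuration
#'
#' Builds an idealized lower-molar enamel-dentine junction ridge curve:
#' `n_fixed` dentine-horn apices (protoconid, metaconid, entoconid,
#' hypoconulid, hypoconid for the default 5) sit at elevated heights above
#' an elliptical crown outline (mesiodistal axis longer than buccolingual),
#' and `n_semi` semilandmarks are interpolated along the marginal-ridge
#' arcs connecting consecutive horns in the cyclic homology order, dipping
#' between horns. Points are ordered horn 1, its following arc, horn 2,
#' ... so the default call yields the 147-point scheme (5 fixed + 142
#' semilandmarks). The configuration is scaled to unit centroid size.
#'
#' When `n_semi` does not divide evenly over the `n_fixed` arcs, the
#' remainder is given to the first arcs (deterministic).
#'
#' @param n_fixed Number of dentine-horn landmarks (>= 3).
#' @param n_semi Number of ridge semilandmarks.
#' @return A [landmark_config] with `specimen_id = "template"`.
#' @export
make_edj_template <- function(n_fixed = 5L, n_semi = 142L) {
  if (n_fixed < 3L) stop("need n_fixed >= 3")
  if (n_semi < 0L) stop("need n_semi >= 0")
  # crown outline: ellipse, mesiodistal (x) elongated
  a <- 1.0; b <- 0.65
  horn_theta <- 2 * pi * (seq_len(n_fixed) - 1) / n_fixed
  horn_height <- 0.35 + 0.05 * cos(2 * horn_theta)  # mild horn asymmetry
  per_arc <- rep(n_semi %/% n_fixed, n_fixed)
  rem <- n_semi %% n_fixed
  if (rem > 0) per_arc[seq_len(rem)] <- per_arc[seq_len(rem)] + 1L
  pts <- list(); kind <- character(0)
  for (i in seq_len(n_fixed)) {
    t0 <- horn_theta[i]
    t1 <- if (i < n_fixed) horn_theta[i + 1] else 2 * pi
    h0 <- horn_height[i]
    h1 <- horn_height[if (i < n_fixed) i + 1 else 1]
    pts[[length(pts) + 1L]] <- c(a * cos(t0), b * sin(t0), h0)
    kind <- c(kind, "fixed")
    if (per_arc[i] > 0) {
      frac <- seq_len(per_arc[i]) / (per_arc[i] + 1)
      th <- t0 + frac * (t1 - t0)
      # ridge dips to ~60% of the horn heights mid-arc
      z <- (1 - frac) * h0 + frac * h1 - 0.4 * sin(pi * frac) * (h0 + h1) / 2
      arc <- cbind(a * cos(th), b * sin(th), z)
      for (j in seq_len(nrow(arc))) {
        pts[[length(pts) + 1L]] <- arc[j, ]
        kind <- c(kind, "semilandmark")
      }
    }
  }
  m <- do.call(rbind, pts)
  m <- center_coords(m)
  m <- m / centroid_size(m)
  landmark_config("template", m, landmark_kind = kind, side = "right")
}

#' Simulation specification for synthetic EDJ datasets
#'
#' The defaults state the simulated world: five groups echoing the study
#' design (three fossil regions plus the two extant species), group sizes
#' from the study's morphometric sample, a group shape effect of 0.2 (in
#' units of consensus centroid size) against per-coordinate landmark noise
#' of 0.005, lognormal size spread of 0.15, roughly half the teeth being
#' left antimeres, and no a posteriori specimens unless requested.
#'
#' @param n_groups Number of groups.
#' @param n_per_group Integer vector (recycled) of specimens per group.
#' @param effect_size Magnitude delta of the group-specific mean-shape
#'   deformation, as a fraction of the (unit) template centroid size.
#' @param noise_sd Per-coordinate Gaussian landmark noise sigma, same
#'   units.
#' @param size_log_sd Standard deviation of log centroid size.
#' @param mirror_fraction Fraction of specimens stored as left antimeres.
#' @param n_posteriori Number of specimens flagged for a posteriori
#'   projection only.
#' @param group_names Optional group labels.
#' @param seed Integer seed driving all randomness.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_groups = 5L,
                            n_per_group = c(9L, 35L, 25L, 20L, 23L),
                            effect_size = 0.2, noise_sd = 0.005,
                            size_log_sd = 0.15, mirror_fraction = 0.5,
                            n_posteriori = 0L,
                            group_names = NULL, seed = 1L) {
  if (n_groups < 1L) stop("need n_groups >= 1")
  n_per_group <- rep_len(as.integer(n_per_group), n_groups)
  if (any(n_per_group < 0L)) stop("negative group size")
  if (effect_size < 0 || noise_sd < 0 || size_log_sd < 0)
    stop("effect_size, noise_sd and size_log_sd must be >= 0")
  if (mirror_fraction < 0 || mirror_fraction > 1)
    stop("mirror_fraction must be in [0, 1]")
  if (is.null(group_names)) {
    base <- c("China", "Vietnam", "Indonesia", "Pongo_abelii",
              "Pongo_pygmaeus")
    group_names <- if (n_groups <= 5L) base[seq_len(n_groups)]
                   else c(base, paste0("group_", 6:n_groups))
  }
  structure(list(n_groups = as.integer(n_groups),
                 n_per_group = n_per_group, effect_size = effect_size,
                 noise_sd = noise_sd, size_log_sd = size_log_sd,
                 mirror_fraction = mirror_fraction,
                 n_posteriori = as.integer(n_posteriori),
                 group_names = group_names, seed = as.integer(seed)),
            class = "simulation_spec")
}

# fixed smooth deformation field for group g on template coordinates:
# per-horn vertical offsets plus mesiodistal elongation of the outline,
# deterministic in the group index. Returns a K x 3 displacement of unit
# Frobenius norm.
group_deformation <- function(template, g) {
  m <- template$coords
  k <- nrow(m)
  horn_idx <- which(template$landmark_kind == "fixed")
  n_horns <- length(horn_idx)
  # smooth weight of each point toward each horn (by angular proximity)
  theta <- atan2(m[, 2], m[, 1])
  horn_theta <- theta[horn_idx]
  offs <- sin(g + 1.7 * seq_len(n_horns))          # per-horn height offsets
  w <- vapply(seq_len(n_horns), function(h) {
    d <- cos(theta - horn_theta[h])
    pmax(d, 0)^3
  }, numeric(k))
  dz <- as.vector(w %*% offs)
  elong <- cos(1.3 * g)                            # mesiodistal stretch
  disp <- cbind(elong * m[, 1], -0.4 * elong * m[, 2], dz)
  disp / sqrt(sum(disp^2))
}

random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(q)
  R <- R %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate an EDJ-like landmark dataset with known group structure
#'
#' Each group's mean shape is the template plus `effect_size` times a
#' fixed, group-specific smooth deformation (per-horn height offsets and
#' mesiodistal elongation — the shape contrasts the canonical axes of the
#' real data express). Specimens add iid Gaussian landmark noise to their
#' group mean, are scaled by a lognormal centroid size, randomly rotated
#' and translated, and a fraction are stored reflected as left antimeres.
#' Optionally the last `n_posteriori` specimens (spread over groups) are
#' flagged for a posteriori projection.
#'
#' @param spec A [simulation_spec].
#' @return A list with `dataset` (an [edj_dataset]) and `truth` (template,
#'   group mean shapes, per-specimen group, true sizes).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  template <- make_edj_template()
  k <- nrow(template$coords)
  group_means <- lapply(seq_len(spec$n_groups), function(g)
    template$coords + spec$effect_size * group_deformation(template, g))
  names(group_means) <- spec$group_names
  configs <- list(); grp <- character(0)
  true_sizes <- numeric(0)
  for (g in seq_len(spec$n_groups)) {
    for (j in seq_len(spec$n_per_group[g])) {
      m <- group_means[[g]] +
        matrix(stats::rnorm(3 * k, sd = spec$noise_sd), k, 3)
      size <- stats::rlnorm(1, meanlog = 0, sdlog = spec$size_log_sd)
      m <- m * size
      m <- m %*% random_rotation()
      m <- sweep(m, 2, stats::rnorm(3, sd = 0.5), `+`)
      is_left <- stats::runif(1) < spec$mirror_fraction
      if (is_left) m[, 1] <- -m[, 1]
      id <- sprintf("%s_%02d", spec$group_names[g], j)
      configs[[id]] <- landmark_config(id, m,
                                       landmark_kind = template$landmark_kind,
                                       side = if (is_left) "left" else "right")
      grp <- c(grp, spec$group_names[g])
      true_sizes <- c(true_sizes, size)
    }
  }
  n <- length(configs)
  posteriori <- rep(FALSE, n)
  if (spec$n_posteriori > 0L) {
    # spread a posteriori flags across groups: last specimen(s) of each
    idx <- unlist(lapply(split(seq_len(n), grp), utils::tail,
                         ceiling(spec$n_posteriori / spec$n_groups)))
    posteriori[sort(idx)[seq_len(min(spec$n_posteriori, length(idx)))]] <- TRUE
  }
  records <- specimen_records(
    names(configs), group = grp,
    side = vapply(configs, function(cf) cf$side, character(1)),
    posteriori_flag = posteriori)
  list(dataset = edj_dataset(configs, records),
       truth = list(template = template, group_means = group_means,
                    group = grp, sizes = true_sizes, spec = spec))
}
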