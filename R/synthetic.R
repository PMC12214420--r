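#' Specification of a planted-parcel synthetic volume
#'
#' The generative model behind all recovery tests: K spatially contiguous
#' parcels grown over a mask, each carrying an i.i.d. Gaussian latent time
#' course; every voxel observes its parcel's latent series plus independent
#' Gaussian noise. Expected within-parcel correlation is
#' `signal_sd^2 / (signal_sd^2 + noise_sd^2)`.
#'
#' @param dims grid dimensions, default `c(12, 12, 8)`.
#' @param K_true number of planted parcels, default 6.
#' @param T_len number of time points, default 200 (>= 3).
#' @param signal_sd latent series standard deviation, default 1.
#' @param noise_sd voxel noise standard deviation, default 0.5 (2:1
#'   signal-to-noise).
#' @param seed RNG seed.
#' @param mask_shape `"full_box"` or `"ellipsoid"` (inscribed).
#' @return An object of class `planted_parcel_spec`.
#' @export
planted_parcel_spec <- function(dims = c(12, 12, 8), K_true = 6, T_len = 200,
                                signal_sd = 1, noise_sd = 0.5, seed = 1,
                                mask_shape = c("full_box", "ellipsoid")) {
  mask_shape <- match.arg(mask_shape)
  stopifnot(T_len >= 3, signal_sd >= 0, noise_sd >= 0, signal_sd + noise_sd > 0,
            K_true >= 1)
  structure(list(dims = as.integer(dims), K_true = as.integer(K_true),
                 T_len = as.integer(T_len), signal_sd = signal_sd,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 mask_shape = mask_shape),
            class = "planted_parcel_spec")
}

spec_mask <- function(spec) {
  d <- spec$dims
  if (spec$mask_shape == "full_box") {
    inside <- array(TRUE, dim = d)
  } else {
    ctr <- (d + 1) / 2
    rad <- d / 2
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    v <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
         ((g$z - ctr[3]) / rad[3])^2
    inside <- array(v <= 1, dim = d)
  }
  voxel_mask(inside)
}

# Seeded region growing: K random seeds, then synchronized growth — each
# round every parcel (in random order) claims the unassigned voxel on its
# frontier closest to its own seed (Euclidean; random tie-break). This is
# a connectivity-constrained Voronoi growth: parcels stay compact and
# blob-like, grow at comparable rates, and are connected in the
# 26-neighbourhood graph by construction — emulating K real contiguous
# functional regions.
grow_parcels <- function(mask, K, graph = NULL) {
  if (is.null(graph)) graph <- build_neighbor_graph(mask)
  n <- mask$n
  if (K > n) stop("K_true = ", K, " exceeds mask size ", n)
  xyz <- mask_coords_mm(mask)
  labels <- integer(n)
  seeds <- sample.int(n, K)
  labels[seeds] <- seq_len(K)
  shuffle <- function(x) if (length(x) > 1L) x[sample.int(length(x))] else x
  frontier <- lapply(seeds, function(s) graph$adjacency[[s]])
  while (any(labels == 0L)) {
    grew <- FALSE
    for (l in shuffle(seq_len(K))) {
      f <- frontier[[l]][labels[frontier[[l]]] == 0L]
      if (length(f) == 0L) { frontier[[l]] <- f; next }
      d2 <- colSums((t(xyz[f, , drop = FALSE]) - xyz[seeds[l], ])^2)
      best <- f[d2 <= min(d2) + 1e-12]
      v <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
      labels[v] <- l
      grew <- TRUE
      nb <- graph$adjacency[[v]]
      frontier[[l]] <- c(f[f != v], nb[labels[nb] == 0L])
    }
    if (!grew) {
      # remaining voxels unreachable from every seed (disconnected mask):
      # attach one to the spatially nearest labeled voxel and keep growing
      rem <- which(labels == 0L)
      lab <- which(labels > 0L)
      d2 <- colSums((t(xyz[lab, , drop = FALSE]) - xyz[rem[1], ])^2)
      l <- labels[lab[which.min(d2)]]
      labels[rem[1]] <- l
      frontier[[l]] <- c(frontier[[l]], graph$adjacency[[rem[1]]])
    }
  }
  canonical_labels(labels)
}

#' Generate a masked 4D volume with planted contiguous parcels
#'
#' @param spec a [planted_parcel_spec()].
#' @return list with `volume` (4D array), `mask` ([voxel_mask()]), `truth`
#'   (ground-truth `partition`), `latent` (K x T latent series), and
#'   `provenance` (spec echo).
#' @export
make_planted_volume <- function(spec) {
  stopifnot(inherits(spec, "planted_parcel_spec"))
  mask <- spec_mask(spec)
  with_seed(spec$seed, {
    labels <- grow_parcels(mask, spec$K_true)
    latent <- matrix(stats::rnorm(spec$K_true * spec$T_len, sd = spec$signal_sd),
                     spec$K_true, spec$T_len)
    noise <- matrix(stats::rnorm(mask$n * spec$T_len, sd = spec$noise_sd),
                    mask$n, spec$T_len)
    series <- latent[labels, , drop = FALSE] + noise
    volume <- array(0, dim = c(spec$dims, spec$T_len))
    flat <- matrix(volume, prod(spec$dims), spec$T_len)
    flat[mask$linear, ] <- series
    volume <- array(flat, dim = c(spec$dims, spec$T_len))
    list(volume = volume, mask = mask,
         truth = new_partition(labels, mask, K = spec$K_true),
         latent = latent,
         provenance = unclass(spec))
  })
}

#' Generate a multi-subject cohort sharing one ground-truth parcel map
#'
#' The parcel map is drawn once from `spec$seed`; each subject gets fresh
#' latent series and noise from the derived seed `spec$seed * 1000 + i`
#' (subject-level determinism). With `share_latent = TRUE` all subjects
#' share the same latent series, so at `subject_noise_sd = 0` their volumes
#' are identical — the degenerate case where the group ensemble must equal
#' each subject's partition.
#'
#' @param spec a [planted_parcel_spec()].
#' @param n_subjects number of subjects, >= 1.
#' @param subject_noise_sd voxel noise sd per subject; default
#'   `spec$noise_sd`.
#' @param share_latent reuse one latent series across subjects.
#' @return list with `volumes` (list of 4D arrays), `mask`, `truth`,
#'   `provenance`.
#' @export
make_cohort <- function(spec, n_subjects, subject_noise_sd = spec$noise_sd,
                        share_latent = FALSE) {
  stopifnot(inherits(spec, "planted_parcel_spec"), n_subjects >= 1)
  mask <- spec_mask(spec)
  labels <- with_seed(spec$seed, grow_parcels(mask, spec$K_true))
  shared_latent <- if (share_latent)
    with_seed(spec$seed + 1L,
              matrix(stats::rnorm(spec$K_true * spec$T_len, sd = spec$signal_sd),
                     spec$K_true, spec$T_len))
  volumes <- lapply(seq_len(n_subjects), function(i) {
    with_seed(spec$seed * 1000L + i, {
      latent <- if (share_latent) shared_latent else
        matrix(stats::rnorm(spec$K_true * spec$T_len, sd = spec$signal_sd),
               spec$K_true, spec$T_len)
      noise <- matrix(stats::rnorm(mask$n * spec$T_len, sd = subject_noise_sd),
                      mask$n, spec$T_len)
      series <- latent[labels, , drop = FALSE] + noise
      flat <- matrix(0, prod(spec$dims), spec$T_len)
      flat[mask$linear, ] <- series
      array(flat, dim = c(spec$dims, spec$T_len))
    })
  })
  list(volumes = volumes, mask = mask,
       truth = new_partition(labels, mask, K = spec$K_true),
       provenance = c(unclass(spec), list(n_subjects = n_subjects,
                                          subject_noise_sd = subject_noise_sd,
                                          share_latent = share_latent)))
}

#' Specification of a two-group classification cohort
#'
#' Features are region-pair FC-like values: a shared per-pair baseline plus
#' Gaussian subject noise. Pairs in `affected_pairs` are shifted by
#' `effect_size` in group 1. Age and sex are drawn per subject and, when
#' `confound_strength > 0`, leaked into a designated pair set disjoint from
#' the affected pairs (half age-linked, half sex-linked).
#'
#' @param n_per_group integer pair, subjects per group (each >= 10).
#' @param N_regions number of regions, default 20.
#' @param affected_pairs m x 2 matrix of region pairs carrying the group
#'   effect; default the first 10 pairs in [region_pair_index()] order.
#' @param effect_size between-group mean FC shift on affected pairs,
#'   default 0.4 (a strongly separable planted effect: per-feature Cohen's
#'   d of 1.6 across the affected pairs).
#' @param feature_noise_sd per-feature subject noise sd, default 0.25.
#' @param confound_strength age/sex leakage coefficient, default 0.
#' @param n_confound_pairs size of the leaked pair set, default 20.
#' @param seed RNG seed.
#' @return An object of class `clf_cohort_spec`.
#' @export
clf_cohort_spec <- function(n_per_group = c(60, 60), N_regions = 20,
                            affected_pairs = NULL, effect_size = 0.4,
                            feature_noise_sd = 0.25, confound_strength = 0,
                            n_confound_pairs = 20, seed = 1) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 10),
            N_regions >= 3, effect_size >= 0, confound_strength >= 0)
  idx <- region_pair_index(N_regions)
  if (is.null(affected_pairs))
    affected_pairs <- as.matrix(idx[1:10, c("i", "j")])
  affected_pairs <- matrix(as.integer(affected_pairs), ncol = 2)
  key <- paste(pmin(affected_pairs[, 1], affected_pairs[, 2]),
               pmax(affected_pairs[, 1], affected_pairs[, 2]))
  if (!all(key %in% paste(idx$i, idx$j)))
    stop("affected_pairs contains pairs outside 1..N_regions")
  structure(list(n_per_group = as.integer(n_per_group),
                 N_regions = as.integer(N_regions),
                 affected_pairs = affected_pairs, effect_size = effect_size,
                 feature_noise_sd = feature_noise_sd,
                 confound_strength = confound_strength,
                 n_confound_pairs = as.integer(n_confound_pairs),
                 seed = as.integer(seed)),
            class = "clf_cohort_spec")
}

#' Generate a two-group classification cohort
#'
#' @param spec a [clf_cohort_spec()].
#' @return list with `ft` (a [feature_table()]), `affected_regions`
#'   (regions incident to an affected pair), `affected_columns`,
#'   `confound_columns`, `provenance`.
#' @export
make_clf_cohort <- function(spec) {
  stopifnot(inherits(spec, "clf_cohort_spec"))
  idx <- region_pair_index(spec$N_regions)
  M <- nrow(idx)
  n <- sum(spec$n_per_group)
  group <- rep(c(0L, 1L), spec$n_per_group)
  key <- paste(idx$i, idx$j)
  aff_cols <- match(paste(pmin(spec$affected_pairs[, 1], spec$affected_pairs[, 2]),
                          pmax(spec$affected_pairs[, 1], spec$affected_pairs[, 2])),
                    key)
  with_seed(spec$seed, {
    baseline <- stats::rnorm(M, mean = 0.25, sd = 0.15)
    features <- matrix(stats::rnorm(n * M, sd = spec$feature_noise_sd), n, M)
    features <- sweep(features, 2, baseline, `+`)
    features[group == 1L, aff_cols] <-
      features[group == 1L, aff_cols] + spec$effect_size
    age <- stats::rnorm(n, mean = 60, sd = 8)
    sex <- stats::rbinom(n, 1, 0.5)
    conf_cols <- integer(0)
    if (spec$confound_strength > 0 && spec$n_confound_pairs > 0) {
      pool <- setdiff(seq_len(M), aff_cols)
      conf_cols <- sample(pool, min(spec$n_confound_pairs, length(pool)))
      half <- length(conf_cols) %/% 2
      age_cols <- conf_cols[seq_len(half)]
      sex_cols <- conf_cols[setdiff(seq_along(conf_cols), seq_len(half))]
      z_age <- (age - mean(age)) / stats::sd(age)
      for (m in age_cols)
        features[, m] <- features[, m] + spec$confound_strength * z_age
      for (m in sex_cols)
        features[, m] <- features[, m] + spec$confound_strength * (sex - 0.5) * 2
    }
    ft <- feature_table(features, group = group, age = age, sex = sex,
                        pair_index = idx)
    list(ft = ft,
         affected_regions = sort(unique(as.integer(spec$affected_pairs))),
         affected_columns = aff_cols,
         confound_columns = conf_cols,
         provenance = c(unclass(spec)[setdiff(names(unclass(spec)), "affected_pairs")],
                        list(affected_pairs = apply(spec$affected_pairs, 1, paste,
                                                    collapse = "-"))))
  })
}

#' Write generator provenance as JSON
#'
#' @param x a list with a `provenance` element (any generator output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_provenance_json <- function(x, path) {
  jsonlite::write_json(x$provenance, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
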