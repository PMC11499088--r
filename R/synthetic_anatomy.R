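# Synthetic LAA-like anatomy generator. Shapes are swept tubes: a circular-arc
# centerline bent by `bend_angle`, a smooth radius profile with Gaussian lobe
# protrusions, closed by tapered end caps (genus 0, watertight by
# construction), plus a band-limited radial displacement field standing in for
# trabecular surface detail. Real trabeculae are through-holes; modelling them
# as high-frequency displacement keeps the topology spherical so that
# registration and reconstruction oracles stay simple, while preserving the
# property under study: fine-scale, class-informative surface structure that
# simplification removes.

#' Anatomy specification
#'
#' Fully determines one synthetic shape; identical specs (including `seed`)
#' regenerate bit-identical meshes.
#'
#' @param label shape class, `"CW"` (chicken-wing-like: long, strongly bent)
#'   or `"NCW"`.
#' @param bend_angle total centerline turning angle in degrees, in [0, 180).
#' @param length centerline arc length in mm.
#' @param radius_profile two-column matrix/data.frame of (arc position in
#'   [0,1], radius in mm) control points, interpolated by a natural spline.
#' @param n_lobes number of Gaussian bump protrusions (secondary lobes).
#' @param lobe_amplitude lobe height in mm.
#' @param detail_amplitude RMS amplitude of the fine-detail displacement, mm;
#'   must be smaller than the minimum profile radius.
#' @param detail_frequency dominant spatial frequency of the detail field,
#'   cycles per mm.
#' @param mesh_resolution target triangle edge length in mm.
#' @param seed integer seed driving every random draw for this shape.
#' @param detail_template_seed seed of the deterministic detail *template*
#'   shared by shapes of the same class (trabecular patterns are anatomically
#'   stereotyped); defaults to a value derived from `seed`.
#' @param detail_template_weight share (0..1) of template vs. shape-specific
#'   random detail.
#' @return object of class `anatomy_spec`.
#' @export
anatomy_spec <- function(label = c("CW", "NCW"),
                         bend_angle = 60,
                         length = 45,
                         radius_profile = cbind(c(0, 0.35, 0.7, 1),
                                                c(6, 7, 6.6, 3.8)),
                         n_lobes = 2L,
                         lobe_amplitude = 2,
                         detail_amplitude = 0.6,
                         detail_frequency = 0.5,
                         mesh_resolution = 0.8,
                         seed = 1L,
                         detail_template_seed = NULL,
                         detail_template_weight = 0.55) {
  label <- match.arg(label)
  radius_profile <- as.matrix(radius_profile)
  spec <- structure(list(
    label = label, bend_angle = bend_angle, length = length,
    radius_profile = radius_profile, n_lobes = as.integer(n_lobes),
    lobe_amplitude = lobe_amplitude, detail_amplitude = detail_amplitude,
    detail_frequency = detail_frequency, mesh_resolution = mesh_resolution,
    seed = as.integer(seed),
    detail_template_seed = if (is.null(detail_template_seed))
      derive_seed(seed, 77L) else as.integer(detail_template_seed),
    detail_template_weight = detail_template_weight
  ), class = "anatomy_spec")
  validate_anatomy_spec(spec)
  spec
}

validate_anatomy_spec <- function(spec) {
  rp <- spec$radius_profile
  if (spec$bend_angle < 0 || spec$bend_angle >= 180)
    stop_md("invalid-spec", "bend_angle must be in [0, 180)")
  if (spec$length <= 0) stop_md("invalid-spec", "length must be positive")
  if (ncol(rp) != 2L || any(rp[, 2] <= 0) || any(rp[, 1] < 0 | rp[, 1] > 1))
    stop_md("invalid-spec", "radius_profile must be (pos in [0,1], radius > 0)")
  if (spec$detail_amplitude < 0)
    stop_md("invalid-spec", "detail_amplitude must be >= 0")
  if (spec$detail_amplitude >= min(rp[, 2]))
    stop_md("invalid-spec",
            "detail_amplitude (%g) must stay below the minimum radius (%g)",
            spec$detail_amplitude, min(rp[, 2]))
  if (spec$n_lobes < 0) stop_md("invalid-spec", "n_lobes must be >= 0")
  if (spec$mesh_resolution <= 0) stop_md("invalid-spec", "mesh_resolution > 0")
  invisible(spec)
}

# Reference surface dimensions used to lay out detail fields in a common
# parametric frame, so that same-class shapes share their template pattern at
# corresponding (u, theta) locations regardless of individual size.
DETAIL_REF_LENGTH <- 45
DETAIL_REF_RADIUS <- 7

# Band-limited random field: sum of J plane waves with unit RMS. The
# circumferential wavenumber is quantised so the field is periodic in theta.
bandlimited_field <- function(freq, seed, J = 14L) {
  with_seed(seed, {
    kmag <- 2 * pi * freq * stats::runif(J, 0.75, 1.25)
    psi <- stats::runif(J, 0, 2 * pi)
    kx <- kmag * cos(psi)
    ky <- round(kmag * sin(psi) * DETAIL_REF_RADIUS) / DETAIL_REF_RADIUS
    list(kx = kx, ky = ky, phase = stats::runif(J, 0, 2 * pi), J = J)
  })
}

eval_field <- function(fld, su, sv) {
  acc <- 0
  for (j in seq_len(fld$J))
    acc <- acc + cos(fld$kx[j] * su + fld$ky[j] * sv + fld$phase[j])
  sqrt(2 / fld$J) * acc
}

# Class detail template: ridge pattern that is fine circumferentially
# (wavelength ~3-4.5 mm, removed by low-density reconstruction smoothing) but
# varying along the axis, where inter-subject correspondence jitter is
# largest -- trabecular ridges follow the pectinate muscle direction. Unit
# RMS; periodic in theta by integer harmonics.
ridge_template <- function(seed, J = 6L) {
  with_seed(seed, list(
    m = sample(9:14, J, replace = TRUE),
    phi = stats::runif(J, 0, 2 * pi),
    q = stats::runif(J, 0.5, 1.5),
    psi = stats::runif(J, 0, 2 * pi),
    J = J
  ))
}

eval_ridge <- function(tp, U, TH) {
  acc <- 0
  for (j in seq_len(tp$J))
    acc <- acc + cos(tp$m[j] * TH + tp$phi[j]) *
      cos(2 * pi * tp$q[j] * U + tp$psi[j])
  2 * acc / sqrt(tp$J)
}

#' Generate one synthetic anatomy mesh
#'
#' @param spec an [anatomy_spec()].
#' @return a watertight, genus-0, outward-oriented [trimesh()].
#' @export
generate_shape <- function(spec) {
  validate_anatomy_spec(spec)
  res <- spec$mesh_resolution
  L <- spec$length
  rp <- spec$radius_profile
  rfun <- stats::splinefun(rp[, 1], rp[, 2], method = "natural")

  n_u <- max(8L, as.integer(round(L / res)))
  r_typ <- mean(rp[, 2])
  n_t <- max(8L, as.integer(round(2 * pi * r_typ / res)))
  u <- seq(0, 1, length.out = n_u + 1L)         # includes both poles
  theta <- seq(0, 2 * pi, length.out = n_t + 1L)[-(n_t + 1L)]

  # lobe placement and per-shape detail field are drawn from the shape seed;
  # lobes first so the detail_amplitude = 0 counterpart shares its macro shape
  lobes <- with_seed(derive_seed(spec$seed, 1L), {
    if (spec$n_lobes > 0)
      list(u = stats::runif(spec$n_lobes, 0.3, 0.85),
           th = stats::runif(spec$n_lobes, 0, 2 * pi),
           su = stats::runif(spec$n_lobes, 0.10, 0.16),
           st = stats::runif(spec$n_lobes, 0.6, 0.9))
    else NULL
  })
  # three-octave detail spectrum: trabecular roughness at the dominant
  # frequency, surface roughness at ~1/2.75 of it, tertiary-lobulation
  # undulations at ~1/4.25 -- progressively removed as the reconstruction
  # kernel grows with the reduction factor
  oct_freq <- spec$detail_frequency / c(1, 2.75, 4.25)
  oct_w <- c(0.6, 0.5, 0.45)
  oct_w <- oct_w / sqrt(sum(oct_w^2))
  noise_flds <- lapply(seq_along(oct_freq), function(k)
    bandlimited_field(oct_freq[k], derive_seed(spec$seed, 2L, k)))
  tmpl_fld <- ridge_template(spec$detail_template_seed)

  # smooth radius on the (u, theta) grid: spline profile + lobes + end taper
  UU <- matrix(u, n_u + 1L, n_t)
  TT <- matrix(theta, n_u + 1L, n_t, byrow = TRUE)
  r_s <- matrix(pmax(rfun(u), 0.3), n_u + 1L, n_t)
  if (!is.null(lobes)) {
    for (k in seq_along(lobes$u)) {
      dth <- atan2(sin(TT - lobes$th[k]), cos(TT - lobes$th[k]))
      r_s <- r_s + spec$lobe_amplitude *
        exp(-(UU - lobes$u[k])^2 / (2 * lobes$su[k]^2) - dth^2 / (2 * lobes$st[k]^2))
    }
  }
  cap_frac <- 0.12
  cap <- function(x) {
    f <- rep(1, length(x))
    lo <- x < cap_frac
    hi <- x > 1 - cap_frac
    f[lo] <- sqrt(pmax(0, 1 - ((cap_frac - x[lo]) / cap_frac)^2))
    f[hi] <- sqrt(pmax(0, 1 - ((x[hi] - (1 - cap_frac)) / cap_frac)^2))
    f
  }
  capf <- matrix(cap(u), n_u + 1L, n_t)
  r_s <- r_s * capf

  # fine detail, tapered at the caps, clamped to avoid self-intersection
  if (spec$detail_amplitude > 0) {
    su <- UU * DETAIL_REF_LENGTH
    sv <- TT * DETAIL_REF_RADIUS
    wt <- spec$detail_template_weight
    noise <- 0
    for (k in seq_along(noise_flds))
      noise <- noise + oct_w[k] * eval_field(noise_flds[[k]], su, sv)
    dd <- (wt * eval_ridge(tmpl_fld, UU, TT) +
             (1 - wt) * noise) / sqrt(wt^2 + (1 - wt)^2)
    dd <- spec$detail_amplitude * dd * capf
    dd <- pmax(pmin(dd, 0.9 * r_s), -0.9 * r_s)
    r_all <- r_s + dd
  } else r_all <- r_s

  # centerline: circular arc of total turn bend_angle in the x-z plane
  phi <- spec$bend_angle * pi / 180
  s <- u * L
  if (phi < 1e-9) {
    cx <- rep(0, length(s)); cz <- s
    tx <- rep(0, length(s)); tz <- rep(1, length(s))
  } else {
    Rc <- L / phi
    a <- s / Rc
    cx <- Rc * (1 - cos(a)); cz <- Rc * sin(a)
    tx <- sin(a); tz <- cos(a)
  }
  # frame: normal N = (cos a, 0, -sin a), binormal B = (0, 1, 0)
  nxv <- if (phi < 1e-9) rep(1, length(s)) else cos(s * phi / L)
  nzv <- if (phi < 1e-9) rep(0, length(s)) else -sin(s * phi / L)

  nv_ring <- n_u - 1L                      # interior rings (poles separate)
  verts <- matrix(0, nv_ring * n_t + 2L, 3)
  for (i in seq_len(nv_ring)) {
    ri <- i + 1L                           # row in grid (skip pole row 1)
    ct <- cos(theta); st <- sin(theta)
    rr <- r_all[ri, ]
    verts[(i - 1L) * n_t + seq_len(n_t), ] <- cbind(
      cx[ri] + rr * (ct * nxv[ri]),
      rr * st,
      cz[ri] + rr * (ct * nzv[ri])
    )
  }
  p0 <- nv_ring * n_t + 1L                 # start pole
  p1 <- nv_ring * n_t + 2L                 # end pole
  verts[p0, ] <- c(cx[1], 0, cz[1])
  verts[p1, ] <- c(cx[n_u + 1L], 0, cz[n_u + 1L])

  faces <- vector("list", nv_ring + 1L)
  ring <- function(i) (i - 1L) * n_t + seq_len(n_t)
  nxt <- c(seq_len(n_t)[-1], 1L)
  r1 <- ring(1L)
  faces[[1]] <- cbind(p0, r1[nxt], r1)     # start fan (outward: -z side)
  for (i in seq_len(nv_ring - 1L)) {
    a_ <- ring(i); b_ <- ring(i + 1L)
    faces[[i + 1L]] <- rbind(cbind(a_, a_[nxt], b_), cbind(a_[nxt], b_[nxt], b_))
  }
  faces[[nv_ring + 1L]] <- cbind(p1, ring(nv_ring), ring(nv_ring)[nxt])
  mesh <- trimesh(verts, do.call(rbind, faces))
  if (mesh_volume(mesh) < 0)
    mesh <- trimesh(mesh$vertices, mesh$faces[, c(1, 3, 2)])
  mesh$normals <- vertex_normals(mesh)
  mesh
}

#' Smooth (detail-free) counterpart of a spec
#'
#' Same macro geometry, lobes and seed, with the fine-detail field switched
#' off; the reference surface for [detail_energy()].
#'
#' @param spec an [anatomy_spec()].
#' @export
smooth_counterpart <- function(spec) {
  spec$detail_amplitude <- 0
  generate_shape(spec)
}

#' RMS fine-detail energy of a mesh against its smooth reference
#'
#' Root-mean-square signed closest-point distance from the vertices of `mesh`
#' to the surface of `smooth_reference`; quantifies how much fine-scale
#' displacement survives a processing step.
#'
#' @param mesh,smooth_reference watertight [trimesh()] objects.
#' @return RMS distance in mm.
#' @export
detail_energy <- function(mesh, smooth_reference) {
  if (!is_watertight(mesh) || !is_watertight(smooth_reference))
    stop_md("invalid-mesh", "detail_energy requires watertight meshes")
  cp <- closest_points(smooth_reference, mesh$vertices)
  sqrt(mean((cp$sign * cp$dist)^2))
}

#' Cohort specification
#'
#' Class-conditional parameter distributions for a synthetic cohort of two
#' macro-shape classes, chicken-wing-like (CW) and non-chicken-wing (NCW).
#' `macro_overlap` moves the class bend-angle means toward each other
#' (0 = fully separated, 1 = identical); `detail_class_coupling` scales how
#' much the detail amplitude/frequency distributions (and the class detail
#' templates) differ between classes, 0 meaning detail carries no class
#' signal.
#'
#' @param n_shapes cohort size (>= 4).
#' @param cw_fraction CW class prevalence; default 21/85.
#' @param macro_overlap overlap of the class bend-angle distributions, [0,1].
#' @param detail_class_coupling strength of class-discriminative detail, >= 0.
#' @param mesh_resolution target edge length of generated meshes, mm.
#' @param detail_amplitude_base,detail_frequency_base class-average detail
#'   parameters (mm, cycles/mm).
#' @param master_seed integer seed for the whole cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_shapes = 85L,
                        cw_fraction = 21 / 85,
                        macro_overlap = 0.75,
                        detail_class_coupling = 1,
                        mesh_resolution = 0.8,
                        detail_amplitude_base = 0.6,
                        detail_frequency_base = 0.5,
                        master_seed = 1L) {
  if (n_shapes < 4L) stop_md("invalid-spec", "n_shapes must be >= 4")
  if (cw_fraction <= 0 || cw_fraction >= 1)
    stop_md("invalid-spec", "cw_fraction must be in (0,1)")
  if (macro_overlap < 0 || macro_overlap > 1)
    stop_md("invalid-spec", "macro_overlap must be in [0,1]")
  if (detail_class_coupling < 0)
    stop_md("invalid-spec", "detail_class_coupling must be >= 0")
  structure(list(
    n_shapes = as.integer(n_shapes), cw_fraction = cw_fraction,
    macro_overlap = macro_overlap, detail_class_coupling = detail_class_coupling,
    mesh_resolution = mesh_resolution,
    detail_amplitude_base = detail_amplitude_base,
    detail_frequency_base = detail_frequency_base,
    master_seed = as.integer(master_seed)
  ), class = "cohort_spec")
}

#' Draw the per-shape anatomy specifications of a cohort
#'
#' The CW label count is `round(n_shapes * cw_fraction)` exactly
#' (deterministic rounding); shape order is a seeded shuffle. Meshes are not
#' generated; see [generate_cohort()].
#'
#' @param cohort a [cohort_spec()].
#' @return list with `labels` and `specs`.
#' @export
cohort_anatomy_specs <- function(cohort) {
  n <- cohort$n_shapes
  n_cw <- as.integer(round(n * cohort$cw_fraction))
  labels <- c(rep("CW", n_cw), rep("NCW", n - n_cw))
  labels <- with_seed(derive_seed(cohort$master_seed, 3L), sample(labels))

  cpl <- cohort$detail_class_coupling
  ov <- cohort$macro_overlap
  bend_half_gap <- 36 * (1 - ov)
  # one detail template per class; identical when coupling is 0
  tmpl_seed <- c(
    CW = derive_seed(cohort$master_seed, 101L),
    NCW = if (cpl > 0) derive_seed(cohort$master_seed, 102L)
          else derive_seed(cohort$master_seed, 101L)
  )

  specs <- vector("list", n)
  for (i in seq_len(n)) {
    cw <- labels[i] == "CW"
    specs[[i]] <- with_seed(derive_seed(cohort$master_seed, 10L, i), {
      bend <- stats::rnorm(1, 72 + if (cw) bend_half_gap else -bend_half_gap, 8)
      bend <- min(max(bend, 5), 165)
      len <- stats::rnorm(1, if (cw) 48 else 43, 3)
      len <- max(len, 25)
      r0 <- stats::rnorm(1, 7, 0.6)
      r0 <- max(r0, 4)
      prof <- cbind(c(0, 0.35, 0.7, 1),
                    r0 * c(0.85, 1, 0.95, 0.55) *
                      exp(stats::rnorm(4, 0, 0.04)))
      amp <- cohort$detail_amplitude_base *
        (if (cw) 1 + 0.25 * cpl else 1 - 0.15 * cpl) * exp(stats::rnorm(1, 0, 0.1))
      freq <- cohort$detail_frequency_base *
        (if (cw) 1 + 0.2 * cpl else 1 - 0.2 * cpl) * exp(stats::rnorm(1, 0, 0.1))
      anatomy_spec(
        label = if (cw) "CW" else "NCW",
        bend_angle = bend, length = len, radius_profile = prof,
        n_lobes = sample(1:3, 1), lobe_amplitude = stats::runif(1, 1.5, 3),
        detail_amplitude = amp, detail_frequency = freq,
        mesh_resolution = cohort$mesh_resolution,
        seed = derive_seed(cohort$master_seed, 20L, i),
        detail_template_seed = tmpl_seed[[if (cw) "CW" else "NCW"]]
      )
    })
  }
  list(labels = labels, specs = specs)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-shape specifications with [cohort_anatomy_specs()] and generates
#' every mesh.
#'
#' @param cohort a [cohort_spec()].
#' @return list with `meshes` (list of [trimesh()]), `labels` (character,
#'   "CW"/"NCW"), `specs` (the per-shape [anatomy_spec()]s) and `ids`.
#' @export
generate_cohort <- function(cohort) {
  drawn <- cohort_anatomy_specs(cohort)
  list(meshes = lapply(drawn$specs, generate_shape),
       labels = drawn$labels, specs = drawn$specs,
       ids = sprintf("shape_%03d", seq_len(cohort$n_shapes)))
}

#' Write a cohort to disk
#'
#' Meshes as binary PLY with per-vertex normals, labels as a
#' `shape_id,label` CSV, and a JSON manifest recording every anatomy spec.
#'
#' @param cohort_data result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort_data$meshes))
    write_mesh(cohort_data$meshes[[i]],
               file.path(dir, paste0(cohort_data$ids[i], ".ply")))
  utils::write.csv(
    data.frame(shape_id = cohort_data$ids, label = cohort_data$labels),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  manifest <- lapply(cohort_data$specs, function(s) {
    s <- unclass(s)
    s$radius_profile <- apply(s$radius_profile, 1, as.numeric, simplify = FALSE)
    s
  })
  names(manifest) <- cohort_data$ids
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read cohort labels from CSV
#' @param path a `shape_id,label` CSV as written by [write_cohort()].
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("shape_id", "label") %in% names(df)))
    stop_md("format-error", "labels CSV must have shape_id,label columns")
  df
}
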