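# Synthetic fluorescence microscopy: procedurally grown branching glial
# cells and planted punctate terminals rendered into multichannel stacks
# with full ground truth. The generator shares its geometric definitions
# (capsule masks, signed distances, the classification rule) with the
# measurement modules, so planted classes are recomputable exactly.

# evaluate code with a private, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Branching glial cell model
#'
#' Parameters of the procedural microglia: a spherical soma and a random
#' binary branching tree of straight tube segments. Branch points occur at
#' exponentially distributed arc-length intervals: a segment of length L
#' branches into two children with probability 1 - exp(-branch_rate * L),
#' up to `max_depth`, which gives a closed-form expected branch count for
#' validation. Segment lengths are Gamma distributed with mean
#' `mean_segment` and coefficient of variation `segment_cv`.
#'
#' @param soma_center (z, y, x) um; set per cell at scene time.
#' @param soma_radius soma radius, um.
#' @param n_primary number of primary processes leaving the soma.
#' @param branch_rate branch probability per um of grown process.
#' @param mean_segment mean inter-branch segment length, um.
#' @param segment_cv coefficient of variation of segment lengths (0 =
#'   deterministic lengths).
#' @param process_radius tube radius of processes, um.
#' @param max_depth maximum branching depth (primary segment = depth 1).
#' @param tortuosity angular dispersion (radians-scale) of segment
#'   directions around their parent direction.
#' @param branch_angle half-angle between sibling branches (radians).
#' @return A `glia_model` list.
#' @export
glia_model <- function(soma_center = NULL, soma_radius = 2.5, n_primary = 4,
                       branch_rate = 0.08, mean_segment = 6,
                       segment_cv = 0.3, process_radius = 0.6,
                       max_depth = 3, tortuosity = 0.3,
                       branch_angle = 0.6) {
  if (soma_radius <= 0 || process_radius <= 0) stop("radii must be > 0")
  if (branch_rate < 0) stop("branch_rate must be >= 0")
  if (n_primary < 1 && max_depth > 0)
    stop("parameters imply zero processes with positive depth")
  structure(list(soma_center = soma_center, soma_radius = soma_radius,
                 n_primary = n_primary, branch_rate = branch_rate,
                 mean_segment = mean_segment, segment_cv = segment_cv,
                 process_radius = process_radius, max_depth = max_depth,
                 tortuosity = tortuosity, branch_angle = branch_angle),
            class = "glia_model")
}

#' Punctate terminal model
#'
#' @param diameter physical spot diameter, um (default 0.8, the calibrated
#'   terminal size).
#' @param intensity peak rendered intensity.
#' @param density mean terminals per cubic micrometer of ROI.
#' @param frac_contact fraction planted in the contact band near a cell
#'   surface.
#' @param frac_engulfed fraction planted inside cells (within the
#'   engulfment shell).
#' @param margin safety margin (um) keeping planted distances away from
#'   the class boundaries, so discretization cannot flip a planted class.
#' @param min_separation minimum pairwise distance (um) between planted
#'   spots; terminals are discrete objects, and spots closer than the
#'   spot diameter are not resolvable by any single-scale detector.
#'   Default one spot diameter.
#' @param sigma rendered Gaussian sd, um; default `(diameter/2)/sqrt(3)`,
#'   the blob scale matched to the stated diameter.
#' @return A `spot_model` list.
#' @export
spot_model <- function(diameter = 0.8, intensity = 100, density = 0.02,
                       frac_contact = 0.1, frac_engulfed = 0.1,
                       margin = 0.15, min_separation = diameter,
                       sigma = NULL) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (frac_contact + frac_engulfed > 1)
    stop("planted fractions must sum to <= 1")
  if (is.null(sigma)) sigma <- (diameter / 2) / sqrt(3)
  structure(list(diameter = diameter, intensity = intensity,
                 density = density, frac_contact = frac_contact,
                 frac_engulfed = frac_engulfed, margin = margin,
                 min_separation = min_separation, sigma = sigma),
            class = "spot_model")
}

#' Noise model: Poisson photon noise then Gaussian read noise
#'
#' @param read_sd additive Gaussian read-noise standard deviation.
#' @param photon_scale photons per intensity unit for Poisson shot noise
#'   (0 disables shot noise).
#' @return A `noise_model` list.
#' @export
noise_model <- function(read_sd = 5, photon_scale = 1) {
  structure(list(read_sd = read_sd, photon_scale = photon_scale),
            class = "noise_model")
}

apply_noise <- function(img, nm) {
  d <- dim(img)
  if (nm$photon_scale > 0)
    img <- rpois(length(img), pmax(img, 0) * nm$photon_scale) / nm$photon_scale
  if (nm$read_sd > 0)
    img <- img + rnorm(length(img), 0, nm$read_sd)
  img <- pmax(img, 0)
  dim(img) <- d
  img
}

unit <- function(v) v / sqrt(sum(v^2))

# n roughly evenly spread unit vectors, randomly rotated
sphere_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  d <- cbind(cos(phi), sin(phi) * sin(theta), sin(phi) * cos(theta))
  q <- qr.Q(qr(matrix(rnorm(9), 3)))  # random rotation
  if (det(q) < 0) q[, 1] <- -q[, 1]
  d %*% q
}

#' Grow a synthetic branching glial cell
#'
#' Grows the branching tree of [glia_model()] under a fixed seed and
#' returns its ground-truth skeleton graph (rooted at the soma center,
#' with radial soma edges connecting the primary processes), the true
#' total process length (sum of process segment lengths, soma excluded),
#' and the true branch count. With a `grid`, also rasterizes the cell mask
#' as the union of the soma ball and tubes of the process radius.
#'
#' @param model a [glia_model()] with `soma_center` set.
#' @param seed integer seed; the same seed reproduces the identical cell.
#' @param grid optional [voxel_grid] for the mask.
#' @return A `glia_cell`: list with `skeleton` (a `skeleton_graph`),
#'   `segments` (per process segment: node indices a, b and radius),
#'   `true_length`, `branch_count`, `model`, and `mask` when `grid` given.
#' @export
grow_glia <- function(model, seed = 1, grid = NULL) with_seed(seed, {
  stopifnot(inherits(model, "glia_model"))
  soma <- model$soma_center
  if (is.null(soma)) stop("model$soma_center must be set")
  # generous preallocation: segments <= n_primary * (2^depth - 1)
  cap <- 1L + model$n_primary * (1L + 2L^model$max_depth)
  nodes <- matrix(NA_real_, cap, 3)
  nodes[1, ] <- soma
  n_nodes <- 1L
  edges <- matrix(NA_integer_, cap, 2)
  n_edges <- 0L
  seg_a <- integer(0); seg_b <- integer(0)
  true_length <- 0; branch_count <- 0L

  draw_len <- function() {
    if (model$segment_cv <= 0) return(model$mean_segment)
    cv2 <- model$segment_cv^2
    stats::rgamma(1, shape = 1 / cv2, scale = model$mean_segment * cv2)
  }

  if (model$max_depth >= 1 && model$n_primary >= 1) {
    dirs <- sphere_dirs(model$n_primary)
    # FIFO queue entries: parent node index, direction, depth
    queue <- vector("list", cap)
    q_head <- 1L; q_tail <- 0L
    for (i in seq_len(model$n_primary)) {
      n_nodes <- n_nodes + 1L
      nodes[n_nodes, ] <- soma + dirs[i, ] * model$soma_radius
      n_edges <- n_edges + 1L
      edges[n_edges, ] <- c(1L, n_nodes)  # radial soma edge
      q_tail <- q_tail + 1L
      queue[[q_tail]] <- list(node = n_nodes, dir = dirs[i, ], depth = 1L)
    }
    while (q_head <= q_tail) {
      it <- queue[[q_head]]; q_head <- q_head + 1L
      L <- draw_len()
      dir <- unit(it$dir + model$tortuosity * rnorm(3))
      n_nodes <- n_nodes + 1L
      nodes[n_nodes, ] <- nodes[it$node, ] + dir * L
      child <- n_nodes
      n_edges <- n_edges + 1L
      edges[n_edges, ] <- c(it$node, child)
      seg_a <- c(seg_a, it$node); seg_b <- c(seg_b, child)
      true_length <- true_length + L
      p_branch <- 1 - exp(-model$branch_rate * L)
      if (it$depth < model$max_depth && runif(1) < p_branch) {
        branch_count <- branch_count + 1L
        u <- unit(crossp(dir, unit(rnorm(3))))
        spread <- tan(model$branch_angle)
        q_tail <- q_tail + 1L
        queue[[q_tail]] <- list(node = child, dir = unit(dir + spread * u),
                                depth = it$depth + 1L)
        q_tail <- q_tail + 1L
        queue[[q_tail]] <- list(node = child, dir = unit(dir - spread * u),
                                depth = it$depth + 1L)
      }
    }
  }
  nodes <- nodes[seq_len(n_nodes), , drop = FALSE]
  edges <- edges[seq_len(n_edges), , drop = FALSE]
  skel <- skeleton_graph(nodes, edges, root = 1L)
  cell <- structure(list(skeleton = skel,
                         segments = cbind(a = seg_a, b = seg_b),
                         true_length = true_length,
                         branch_count = branch_count, model = model),
                    class = "glia_cell")
  if (!is.null(grid)) cell$mask <- rasterize_cell(cell, grid)
  cell
})

# capsule set (soma ball + process tubes) of one or more cells
cell_capsules <- function(cells) {
  if (inherits(cells, "glia_cell")) cells <- list(cells)
  A <- NULL; B <- NULL; R <- NULL; owner <- integer(0)
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    s <- cl$model$soma_center
    A <- rbind(A, s); B <- rbind(B, s); R <- c(R, cl$model$soma_radius)
    owner <- c(owner, ci)
    if (nrow(cl$segments)) {
      A <- rbind(A, cl$skeleton$nodes[cl$segments[, "a"], , drop = FALSE])
      B <- rbind(B, cl$skeleton$nodes[cl$segments[, "b"], , drop = FALSE])
      R <- c(R, rep(cl$model$process_radius, nrow(cl$segments)))
      owner <- c(owner, rep(ci, nrow(cl$segments)))
    }
  }
  list(A = A, B = B, R = R, owner = owner)
}

#' @rdname grow_glia
#' @param cell a `glia_cell`.
#' @export
rasterize_cell <- function(cell, grid) {
  caps <- cell_capsules(cell)
  m <- array(0L, grid$shape)
  for (s in seq_along(caps$R))
    cpp_add_capsule(m, grid$shape, grid$voxel_size,
                    caps$A[s, ], caps$B[s, ], caps$R[s])
  m <- m == 1L
  dim(m) <- grid$shape
  m
}

# exact signed distance (um) from points (n x 3) to the union of cells;
# also the nearest cell id. No cells: +Inf / NA.
true_signed_distance <- function(cells, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (length(cells) == 0)
    return(list(d = rep(Inf, nrow(pts)), cell = rep(NA_integer_, nrow(pts))))
  caps <- cell_capsules(cells)
  d <- rep(Inf, nrow(pts)); cell <- rep(NA_integer_, nrow(pts))
  for (ci in unique(caps$owner)) {
    sel <- caps$owner == ci
    di <- cpp_dist_to_capsules(pts, caps$A[sel, , drop = FALSE],
                               caps$B[sel, , drop = FALSE], caps$R[sel])
    better <- di < d
    d[better] <- di[better]; cell[better] <- ci
  }
  list(d = d, cell = cell)
}

# Plant spot centroids with prescribed class fractions. Planted distances
# keep `margin` um away from every class boundary so that voxel-level
# measurement cannot flip a class. Must be called inside with_seed().
place_spots <- function(sm, cells, grid, roi,
                        contact_max = 1, engulf_shell = 0.5,
                        mode = "shell") {
  vol <- roi_volume(roi, grid)
  n <- rpois(1, sm$density * vol)
  if (n == 0)
    return(data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), class = character(), d = numeric(),
                      cell = integer()))
  have_cells <- length(cells) > 0
  n_eng <- if (have_cells) round(sm$frac_engulfed * n) else 0L
  n_con <- if (have_cells) round(sm$frac_contact * n) else 0L
  n_free <- n - n_eng - n_con
  m <- sm$margin
  border <- sm$diameter  # keep spots clear of the stack border
  ext <- grid_extent(grid)
  placed <- matrix(NA_real_, 0, 3)  # accepted spots of every class

  in_domain <- function(p) {
    all(p > border) && all(p < ext - border) &&
      roi_contains(roi, grid, matrix(p, 1))
  }
  separated <- function(p) {
    nrow(placed) == 0 ||
      min(colSums((t(placed) - p)^2)) >= sm$min_separation^2
  }
  caps <- if (have_cells) cell_capsules(cells) else NULL
  seg_len <- if (have_cells)
    pmax(sqrt(rowSums((caps$B - caps$A)^2)), 2 * caps$R) else NULL

  sample_band <- function(lo, hi, count) {
    got <- 0L
    guard <- 0
    while (got < count && guard < 500 * count + 500) {
      guard <- guard + 1
      # capsules weighted by length so spots spread over the arbor
      s <- sample.int(length(caps$R), 1, prob = seg_len)
      a <- caps$A[s, ]; b <- caps$B[s, ]; r <- caps$R[s]
      t <- runif(1)
      axis_pt <- a + t * (b - a)
      e <- b - a
      u <- unit(rnorm(3))
      if (sum(e^2) > 0) {
        ee <- unit(e)
        u <- u - sum(u * ee) * ee
        if (sqrt(sum(u^2)) < 1e-6) next
        u <- unit(u)
      }
      off <- runif(1, lo, hi)
      p <- axis_pt + u * (r + off)
      if (!in_domain(p) || !separated(p)) next
      dtrue <- true_signed_distance(cells, matrix(p, 1))$d
      if (dtrue > lo + 1e-9 && dtrue < hi - 1e-9) {
        placed <<- rbind(placed, p)
        got <- got + 1L
      }
    }
    got
  }
  sample_free <- function(count) {
    got <- 0L
    guard <- 0
    while (got < count && guard < 500 * count + 500) {
      guard <- guard + 1
      p <- c(runif(1, border, ext[1] - border),
             runif(1, border, ext[2] - border),
             runif(1, border, ext[3] - border))
      if (!roi_contains(roi, grid, matrix(p, 1)) || !separated(p)) next
      if (have_cells &&
          true_signed_distance(cells, matrix(p, 1))$d <= contact_max + m)
        next
      placed <<- rbind(placed, p)
      got <- got + 1L
    }
    got
  }

  k_eng <- if (n_eng > 0) sample_band(-engulf_shell + m, -m, n_eng) else 0L
  k_con <- if (n_con > 0) sample_band(m, contact_max - m, n_con) else 0L
  k_fre <- if (n_free > 0) sample_free(n_free) else 0L

  pts <- placed[seq_len(k_eng + k_con + k_fre), , drop = FALSE]
  td <- true_signed_distance(cells, pts)
  cl <- classify_distance(ifelse(is.finite(td$d), td$d, contact_max + 100),
                          contact_max, engulf_shell, mode)
  data.frame(id = seq_len(nrow(pts)), z = pts[, 1], y = pts[, 2],
             x = pts[, 3], class = as.character(cl$class), d = td$d,
             cell = td$cell)
}

#' Render a synthetic scene into a multichannel stack
#'
#' The microglia channel is the union of rasterized cell masks times
#' `iba1_intensity`, blurred with a separable Gaussian PSF; the terminal
#' channel is a sum of Gaussian spots of the stated physical diameter at
#' the planted centroids; both then receive Poisson photon noise and
#' Gaussian read noise. Ground-truth spot classes are computed from exact
#' capsule geometry with the same [classify_distance()] rule the
#' measurement side uses, and planted distances stay `margin` um away
#' from every class boundary.
#'
#' @param cells list of `glia_cell` objects (may be empty).
#' @param spots a [spot_model()], or NULL for no terminal channel.
#' @param grid the [voxel_grid].
#' @param noise a [noise_model()].
#' @param psf PSF standard deviations (z, y, x) in um; all > 0 unless the
#'   whole vector is 0 (no blur).
#' @param seed scene seed.
#' @param roi optional [roi_bounds()]; defaults to the full grid.
#' @param iba1_intensity rendered intensity of the cell mask.
#' @param cd68 optional list(`n_per_cell`, `radius`, `intensity`): plants
#'   CD68 puncta (balls) centered on process axes inside each cell.
#' @param contact_max,engulf_shell,mode classification rule used for the
#'   planted ground truth (defaults match [classify_spots()]).
#' @param spot_centers optional n x 3 matrix (z, y, x um) of fixed spot
#'   centroids, overriding the random placement law of `spots` (whose
#'   diameter/intensity/sigma still control rendering); classes are still
#'   computed from the true geometry.
#' @param metadata metadata list stored in the stack.
#' @return List with `stack` (a [multichannel_stack]) and `truth`: `cells`
#'   (the `glia_cell` list), `spots` (planted table with class, signed
#'   distance, nearest cell), `cd68` (per-cell planted volumes, um^3),
#'   `clipped` (any cell geometry outside the grid).
#' @export
render_scene <- function(cells, spots, grid, noise = noise_model(),
                         psf = c(0.3, 0.15, 0.15), seed = 1, roi = NULL,
                         iba1_intensity = 100, cd68 = NULL,
                         contact_max = 1, engulf_shell = 0.5,
                         mode = "shell", spot_centers = NULL,
                         metadata = list()) with_seed(seed + 1L, {
  if (any(psf < 0) || (any(psf == 0) && any(psf > 0)))
    stop("PSF sd must be positive (or all zero for no blur)")
  if (iba1_intensity < 0) stop("negative intensities")
  if (is.null(roi)) roi <- roi_full(grid)
  ext <- grid_extent(grid)

  union_mask <- array(FALSE, grid$shape)
  clipped <- FALSE
  for (cl in cells) {
    m <- if (!is.null(cl$mask)) cl$mask else rasterize_cell(cl, grid)
    union_mask <- union_mask | m
    if (any(cl$skeleton$nodes < 0) ||
        any(sweep(cl$skeleton$nodes, 2, ext, ">"))) clipped <- TRUE
  }
  iba1 <- union_mask * iba1_intensity
  dim(iba1) <- grid$shape
  if (any(psf > 0)) iba1 <- gauss3d(iba1, grid, psf)
  iba1 <- apply_noise(iba1, noise)

  channels <- list(iba1 = iba1)
  truth_spots <- NULL
  if (!is.null(spots)) {
    truth_spots <- if (!is.null(spot_centers)) {
      pts <- matrix(as.numeric(spot_centers), ncol = 3)
      td <- true_signed_distance(cells, pts)
      cl <- classify_distance(ifelse(is.finite(td$d), td$d,
                                     contact_max + 100),
                              contact_max, engulf_shell, mode)
      data.frame(id = seq_len(nrow(pts)), z = pts[, 1], y = pts[, 2],
                 x = pts[, 3], class = as.character(cl$class), d = td$d,
                 cell = td$cell)
    } else {
      place_spots(spots, cells, grid, roi, contact_max, engulf_shell, mode)
    }
    agrp <- array(0, grid$shape)
    sg <- rep(spots$sigma, length.out = 3)
    for (s in seq_len(nrow(truth_spots)))
      cpp_add_gaussian(agrp, grid$shape, grid$voxel_size,
                       c(truth_spots$z[s], truth_spots$y[s],
                         truth_spots$x[s]),
                       sg, spots$intensity)
    channels$agrp <- apply_noise(agrp, noise)
  }

  truth_cd68 <- NULL
  if (!is.null(cd68) && length(cells) > 0) {
    ch <- array(0L, grid$shape)
    vols <- numeric(length(cells))
    for (ci in seq_along(cells)) {
      cl <- cells[[ci]]
      caps <- cell_capsules(cl)
      pm <- array(0L, grid$shape)
      for (p in seq_len(cd68$n_per_cell)) {
        s <- sample.int(length(caps$R), 1)
        t <- runif(1)
        ctr <- caps$A[s, ] + t * (caps$B[s, ] - caps$A[s, ])
        cpp_add_capsule(pm, grid$shape, grid$voxel_size, ctr, ctr,
                        cd68$radius)
      }
      cm <- if (!is.null(cl$mask)) cl$mask else rasterize_cell(cl, grid)
      pm <- (pm == 1L) & cm
      vols[ci] <- sum(pm) * voxel_volume(grid)
      ch[pm] <- 1L
    }
    cd68_img <- ch * cd68$intensity
    dim(cd68_img) <- grid$shape
    channels$cd68 <- apply_noise(cd68_img, noise)
    truth_cd68 <- data.frame(cell = seq_along(cells), true_volume = vols)
  }

  list(stack = multichannel_stack(channels, grid, metadata),
       truth = list(cells = cells, spots = truth_spots, cd68 = truth_cd68,
                    clipped = clipped))
})

#' Sample points with a minimum pairwise separation
#'
#' Rejection-samples `n` uniform points in the box `[lower, upper]` (z, y,
#' x um) keeping every pair at least `min_sep` apart. Uses the current RNG
#' state. Useful for planting non-overlapping benchmark spots.
#'
#' @param n number of points.
#' @param lower,upper numeric length-3 box corners (um).
#' @param min_sep minimum pairwise Euclidean distance (um).
#' @param max_tries give up (error) after this many rejections.
#' @return n x 3 matrix.
#' @export
sample_separated_points <- function(n, lower, upper, min_sep,
                                    max_tries = 10000 * n) {
  pts <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(pts) < n) {
    tries <- tries + 1
    if (tries > max_tries) stop("could not place separated points")
    p <- runif(3, lower, upper)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - p)^2))) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

#' Two-group cohort specification
#'
#' Describes a simulated imaging cohort: named groups (each a
#' [glia_model()] / [spot_model()] pair), animals per group, stacks per
#' animal, cells per stack, acquisition grid, noise, PSF and a master
#' seed. Per-animal seeds are derived deterministically from the master
#' seed (`master + 100003 * animal_index`), so the cohort is reproducible
#' end to end and animals are independent.
#'
#' @param groups named list; each element is a list with fields `glia`
#'   (a [glia_model()], `soma_center` ignored), optional `spots`
#'   (a [spot_model()] or NULL), optional `cells_per_stack` (default 1).
#' @param animals_per_group >= 2.
#' @param stacks_per_animal default 1.
#' @param grid the acquisition [voxel_grid].
#' @param noise a [noise_model()].
#' @param psf PSF sd (z, y, x) um.
#' @param iba1_intensity rendered cell intensity.
#' @param cd68 optional CD68 plant (see [render_scene()]).
#' @param master_seed integer master seed.
#' @param age,region metadata labels stamped on every stack.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, animals_per_group = 4,
                        stacks_per_animal = 1,
                        grid = voxel_grid(c(96, 96, 96), c(0.3, 0.3, 0.3)),
                        noise = noise_model(), psf = c(0.3, 0.15, 0.15),
                        iba1_intensity = 100, cd68 = NULL, master_seed = 1,
                        age = "P16", region = "PVH") {
  if (animals_per_group < 2) stop("need >= 2 animals per group")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  structure(list(groups = groups, animals_per_group = animals_per_group,
                 stacks_per_animal = stacks_per_animal, grid = grid,
                 noise = noise, psf = psf,
                 iba1_intensity = iba1_intensity, cd68 = cd68,
                 master_seed = master_seed, age = age, region = region),
            class = "cohort_spec")
}

# deterministic, well-separated soma positions for n cells in a grid
soma_positions <- function(n, grid) {
  ext <- grid_extent(grid)
  if (n == 1) return(matrix(ext / 2, 1, 3))
  f <- seq(0.3, 0.7, length.out = n)
  cbind(ext[1] / 2, ext[2] * f, ext[3] * rev(f))
}

#' Ready-made two-group cohort specifications
#'
#' Study-condition presets used throughout the package's validation, all
#' emulating a two-group (NCD vs MHFD) developmental imaging design with
#' effect magnitudes of the size reported for diet-driven microglial
#' remodeling:
#'
#' * `"morphometry"`: one ramified cell per stack, 72 um field at 0.5 um
#'   voxels, two stacks per animal. Group MHFD is a spatial rescaling of
#'   group NCD processes — mean segment length x 1.87 with branch rate
#'   / 1.87, leaving the branching law untouched — so the planted
#'   group ratio of mean total process length is exactly 1.87 (an 87%
#'   increase), with mild somatic hypertrophy.
#' * `"terminals"`: punctate 0.8 um terminals only, 19.2 um field at
#'   0.2 um voxels; group MHFD density is 1.61 x group NCD (a 61%
#'   increase) around a realistic 15 per 1000 um^3 baseline.
#' * `"engulfment"`: one compact cell plus terminals with 30% planted
#'   engulfed and 20% planted contacts, single group, 24 um field at
#'   0.25 um voxels.
#'
#' @param type which preset.
#' @param animals_per_group animals per group (default 20).
#' @param master_seed master seed.
#' @return A [cohort_spec()].
#' @export
example_cohort_spec <- function(type = c("morphometry", "terminals",
                                         "engulfment"),
                                animals_per_group = 20, master_seed = 1) {
  type <- match.arg(type)
  if (type == "morphometry") {
    base <- glia_model(soma_radius = 2.5, n_primary = 4, branch_rate = 0.4,
                       mean_segment = 4, segment_cv = 0.3,
                       process_radius = 0.6, max_depth = 3,
                       tortuosity = 0.3)
    big <- base
    big$mean_segment <- base$mean_segment * 1.87
    big$branch_rate <- base$branch_rate / 1.87
    big$soma_radius <- 2.8
    cohort_spec(
      groups = list(NCD = list(glia = base), MHFD = list(glia = big)),
      animals_per_group = animals_per_group, stacks_per_animal = 2,
      grid = voxel_grid(c(144, 144, 144), c(0.5, 0.5, 0.5)),
      noise = noise_model(read_sd = 5, photon_scale = 1),
      psf = c(0.3, 0.15, 0.15), master_seed = master_seed)
  } else if (type == "terminals") {
    mk <- function(dens) list(glia = NULL,
                              spots = spot_model(density = dens,
                                                 frac_contact = 0,
                                                 frac_engulfed = 0))
    cohort_spec(
      groups = list(NCD = mk(0.015), MHFD = mk(0.015 * 1.61)),
      animals_per_group = animals_per_group, stacks_per_animal = 1,
      grid = voxel_grid(c(96, 96, 96), c(0.2, 0.2, 0.2)),
      noise = noise_model(read_sd = 10, photon_scale = 1),
      psf = c(0, 0, 0), master_seed = master_seed)
  } else {
    small <- glia_model(soma_radius = 2.2, n_primary = 4,
                        branch_rate = 0.3, mean_segment = 3,
                        segment_cv = 0.3, process_radius = 0.6,
                        max_depth = 2)
    cohort_spec(
      groups = list(NCD = list(
        glia = small,
        # density kept low enough that spots planted on the one cell
        # stay farther apart than the spot diameter, i.e. resolvable
        spots = spot_model(density = 0.006, frac_engulfed = 0.3,
                           frac_contact = 0.2))),
      animals_per_group = animals_per_group, stacks_per_animal = 1,
      grid = voxel_grid(c(96, 96, 96), c(0.25, 0.25, 0.25)),
      noise = noise_model(read_sd = 5, photon_scale = 1),
      psf = c(0.2, 0.12, 0.12), master_seed = master_seed)
  }
}

#' Generate a simulated cohort
#'
#' Runs the full generator over every group, animal and stack of a
#' [cohort_spec()]. Stacks can be written to `out_dir` as OME-TIFF (with
#' per-stack ground-truth rows collected into tables), kept in memory, or
#' streamed through `callback(scene, info)` without being stored, which
#' keeps large cohorts in constant memory.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; stacks are written as
#'   `<group>_<animal>_s<stack>.ome.tif` plus `gt_cells.csv` /
#'   `gt_spots.csv` ground-truth tables.
#' @param callback optional `function(scene, info)` called per stack.
#' @param keep_scenes keep every scene in the returned list (memory!).
#' @return List with `manifest` (one row per stack), `gt_cells` (per-cell
#'   ground truth: true process length, branch count, Sholl complexity of
#'   the true skeleton, mask volume, territory of the true nodes),
#'   `gt_spots` (per planted spot), and `scenes` when `keep_scenes`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, callback = NULL,
                            keep_scenes = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- NULL; gt_cells <- NULL; gt_spots <- NULL
  scenes <- list()
  animal_idx <- 0L
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    gdef <- spec$groups[[gi]]
    ncell <- if (!is.null(gdef$cells_per_stack)) gdef$cells_per_stack else 1L
    for (a in seq_len(spec$animals_per_group)) {
      animal_idx <- animal_idx + 1L
      animal <- sprintf("%s_a%02d", gname, a)
      aseed <- (spec$master_seed + 100003 * animal_idx) %% 2147483647
      for (s in seq_len(spec$stacks_per_animal)) {
        sseed <- (aseed + 503 * (s - 1L)) %% 2147483647
        somas <- soma_positions(ncell, spec$grid)
        cells <- if (is.null(gdef$glia)) list() else
          lapply(seq_len(ncell), function(ci) {
            mdl <- gdef$glia
            mdl$soma_center <- somas[ci, ]
            grow_glia(mdl, seed = sseed + 7L * ci, grid = spec$grid)
          })
        sc <- render_scene(cells, gdef$spots, spec$grid,
                           noise = spec$noise, psf = spec$psf,
                           seed = sseed,
                           iba1_intensity = spec$iba1_intensity,
                           cd68 = spec$cd68,
                           metadata = list(animal = animal, group = gname,
                                           region = spec$region,
                                           age = spec$age))
        path <- NA_character_
        if (!is.null(out_dir)) {
          # manifest records the file name only, so a cohort directory can
          # be moved (and regenerated cohorts compare identical)
          path <- sprintf("%s_s%02d.ome.tif", animal, s)
          write_stack(sc$stack, file.path(out_dir, path))
        }
        info <- list(group = gname, animal = animal, stack = s,
                     seed = sseed, path = path)
        for (ci in seq_along(cells)) {
          cl <- cells[[ci]]
          sh <- sholl_profile(cl$skeleton, step = 1)
          terr <- tryCatch(territory_volume(cl$skeleton),
                           error = function(e) NA_real_)
          gt_cells <- rbind(gt_cells, data.frame(
            group = gname, animal = animal, stack = s, cell = ci,
            true_length = cl$true_length,
            branch_count = cl$branch_count,
            complexity = sh$complexity,
            mask_volume = sum(cl$mask) * voxel_volume(spec$grid),
            territory = terr))
        }
        if (!is.null(sc$truth$spots) && nrow(sc$truth$spots)) {
          sp <- sc$truth$spots
          sp$group <- gname; sp$animal <- animal; sp$stack <- s
          gt_spots <- rbind(gt_spots, sp)
        }
        if (!is.null(callback)) callback(sc, info)
        if (keep_scenes) scenes[[length(scenes) + 1L]] <- sc
        manifest <- rbind(manifest, data.frame(
          group = gname, animal = animal, stack = s, seed = sseed,
          path = path, n_cells = length(cells),
          n_spots = if (is.null(sc$truth$spots)) 0L
                    else nrow(sc$truth$spots)))
      }
    }
  }
  if (!is.null(out_dir)) {
    write_animal_table(gt_cells, file.path(out_dir, "gt_cells.csv"))
    if (!is.null(gt_spots))
      write_animal_table(gt_spots, file.path(out_dir, "gt_spots.csv"))
    write_animal_table(manifest, file.path(out_dir, "manifest.csv"))
  }
  out <- list(manifest = manifest, gt_cells = gt_cells, gt_spots = gt_spots,
              dir = out_dir)
  if (keep_scenes) out$scenes <- scenes
  out
}
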