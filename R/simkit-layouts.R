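## Ground-truth emitter layouts.
##
## An emitter model is a data.frame of docking-site coordinates (nm) with a
## role per site (target / fiducial / calibration_single), a structure id
## grouping sites that belong to one physical object, and a free-form
## structure kind. The field of view is carried as an attribute so that
## downstream stages can validate positions.

#' Construct an emitter model from explicit site coordinates
#'
#' Low-level constructor for custom ground-truth layouts; the
#' `make_*_layout()` generators cover the standard geometries.
#'
#' @param x,y,z site coordinates in nm (`z` defaults to 0).
#' @param role per-site role: `"target"`, `"fiducial"` or
#'   `"calibration_single"`.
#' @param structure_id non-negative integer grouping sites into physical
#'   structures.
#' @param structure_kind free-form label (e.g. `"origami"`, `"npc"`,
#'   `"vesicle"`, `"isolated"`).
#' @param fov field of view `c(width, height)` in nm, carried as an
#'   attribute and used for validation.
#' @return An `emitter_model` data.frame.
#' @export
emitter_model <- function(x, y, z = 0, role = "target", structure_id = 0L,
                          structure_kind = "isolated", fov = NULL) {
  new_emitter_model(x, y, z, role, structure_id, structure_kind, fov)
}

new_emitter_model <- function(x, y, z = 0, role = "target", structure_id = 0L,
                              structure_kind = "isolated", fov = NULL) {
  n <- length(x)
  df <- data.frame(
    x = as.double(x), y = as.double(y), z = rep_len(as.double(z), n),
    role = rep_len(as.character(role), n),
    structure_id = rep_len(as.integer(structure_id), n),
    structure_kind = rep_len(as.character(structure_kind), n),
    stringsAsFactors = FALSE
  )
  attr(df, "fov") <- fov
  class(df) <- c("emitter_model", "data.frame")
  validate_emitter_model(df)
  df
}

validate_emitter_model <- function(model) {
  stopifnot(is.data.frame(model))
  req <- c("x", "y", "z", "role", "structure_id", "structure_kind")
  miss <- setdiff(req, names(model))
  if (length(miss)) stop_arg("emitter model is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(model) == 0) return(invisible(model))
  if (!all(is.finite(model$x)) || !all(is.finite(model$y)) || !all(is.finite(model$z)))
    stop_arg("emitter coordinates must be finite")
  if (!all(model$role %in% c("target", "fiducial", "calibration_single")))
    stop_arg("unknown emitter role")
  fov <- attr(model, "fov")
  if (!is.null(fov)) {
    if (any(model$x < 0 | model$x > fov[1] | model$y < 0 | model$y > fov[2]))
      stop_arg("emitter sites fall outside the declared field of view")
  }
  sid <- model$structure_id[model$role == "calibration_single"]
  if (length(sid)) {
    cnt <- table(model$structure_id)[as.character(unique(sid))]
    if (any(cnt != 1)) stop_arg("calibration_single structures must contain exactly one site")
  }
  invisible(model)
}

# Rejection-sample `n` structure centers inside `fov` with a minimum
# mutual separation and a margin to the border.
place_centers_ <- function(n, fov, min_sep, margin, max_tries = 5000L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  if (fov[1] <= 2 * margin || fov[2] <= 2 * margin)
    stop_arg("field of view (%g x %g nm) too small for structures of extent %g nm",
             fov[1], fov[2], 2 * margin)
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop_arg(paste0("placement error: could not place %d structures at minimum ",
                      "separation %g nm in a %g x %g nm field of view"),
               n, min_sep, fov[1], fov[2])
    px <- runif(1, margin, fov[1] - margin)
    py <- runif(1, margin, fov[2] - margin)
    if (length(cx) == 0 || all((px - cx)^2 + (py - cy)^2 >= min_sep^2)) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  cbind(cx, cy)
}

rot2_ <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Ground-truth layout of DNA-origami docking-site structures
#'
#' Places rigid DNA-origami designs at random positions and orientations.
#' The `three_pair` design carries six collinear docking sites arranged as
#' three pairs with intra-pair separations of 10, 17 and 10 nm and an
#' overall extent of 53 nm (edge pairs at the extremes, the widest pair in
#' the middle). The `single_pair_6nm` design carries two sites 6 nm apart,
#' the classical test of single-digit-nanometre resolvability.
#'
#' @param n_structures number of origami to place (may be 0).
#' @param design `"three_pair"` or `"single_pair_6nm"`.
#' @param fov field of view, `c(width, height)` in nm.
#' @param seed integer seed; layouts are reproducible given `seed`.
#' @param min_sep minimum center-to-center separation between origami (nm).
#' @return An `emitter_model` data.frame (x, y, z in nm; role;
#'   structure_id; structure_kind = `"origami"`).
#' @examples
#' m <- make_origami_layout(3, "three_pair", fov = c(5000, 5000), seed = 1)
#' table(m$structure_id)
#' @export
make_origami_layout <- function(n_structures,
                                design = c("three_pair", "single_pair_6nm"),
                                fov = c(20000, 20000), seed = 1L,
                                min_sep = 200) {
  design <- match.arg(design)
  if (!is_count(n_structures)) stop_arg("n_structures must be a non-negative integer")
  if (n_structures == 0)
    return(new_emitter_model(numeric(0), numeric(0), fov = fov,
                             structure_kind = character(0), role = character(0),
                             structure_id = integer(0)))
  # local site coordinates (nm), centered on the structure center
  local <- switch(design,
    three_pair = {
      xs <- c(0, 10, 18, 35, 43, 53) # pairs: {0,10} {18,35} {43,53}
      cbind(xs - mean(range(xs)), rep(0, 6))
    },
    single_pair_6nm = cbind(c(-3, 3), c(0, 0))
  )
  half_extent <- max(sqrt(rowSums(local^2)))
  with_seed_(seed, {
    ctr <- place_centers_(n_structures, fov, min_sep, margin = half_extent + 1)
    pieces <- lapply(seq_len(n_structures), function(i) {
      th <- runif(1, 0, 2 * pi)
      p <- local %*% t(rot2_(th))
      cbind(p[, 1] + ctr[i, 1], p[, 2] + ctr[i, 2], i - 1L)
    })
    all <- do.call(rbind, pieces)
    new_emitter_model(all[, 1], all[, 2], role = "target",
                      structure_id = all[, 3], structure_kind = "origami",
                      fov = fov)
  })
}

#' Ground-truth layout of nuclear-pore-like rings
#'
#' Each structure is one ring of eight docking-site pairs at 45 degree
#' angular spacing, every pair separated tangentially by
#' `pair_separation` (16 sites per ring). This emulates the eightfold
#' arrangement of Nup96 pairs on one ring of the nuclear pore complex,
#' where pairs are spaced 12 nm laterally.
#'
#' @param n_structures number of rings.
#' @param ring_diameter ring diameter in nm (default 107, the scale of the
#'   cytoplasmic Nup96 ring).
#' @param pair_separation within-pair site distance in nm (default 12).
#' @inheritParams make_origami_layout
#' @return An `emitter_model` with `structure_kind = "npc"`.
#' @export
make_npc_layout <- function(n_structures, ring_diameter = 107,
                            pair_separation = 12, fov = c(20000, 20000),
                            seed = 1L, min_sep = 400) {
  if (!is_count(n_structures)) stop_arg("n_structures must be a non-negative integer")
  if (!is_pos_num(ring_diameter) || !is_pos_num(pair_separation) ||
      ring_diameter <= pair_separation)
    stop_arg("need ring_diameter > pair_separation > 0")
  if (n_structures == 0)
    return(new_emitter_model(numeric(0), numeric(0), fov = fov,
                             structure_kind = character(0), role = character(0),
                             structure_id = integer(0)))
  R <- ring_diameter / 2
  ang <- (0:7) * pi / 4
  # pair j centered at angle ang[j]; sites offset +-s/2 along the tangent
  px <- as.vector(rbind(R * cos(ang) - pair_separation / 2 * sin(ang),
                        R * cos(ang) + pair_separation / 2 * sin(ang)))
  py <- as.vector(rbind(R * sin(ang) + pair_separation / 2 * cos(ang),
                        R * sin(ang) - pair_separation / 2 * cos(ang)))
  local <- cbind(px, py)
  half_extent <- max(sqrt(rowSums(local^2)))
  with_seed_(seed, {
    ctr <- place_centers_(n_structures, fov, min_sep, margin = half_extent + 1)
    pieces <- lapply(seq_len(n_structures), function(i) {
      th <- runif(1, 0, 2 * pi)
      p <- local %*% t(rot2_(th))
      cbind(p[, 1] + ctr[i, 1], p[, 2] + ctr[i, 2], i - 1L)
    })
    all <- do.call(rbind, pieces)
    new_emitter_model(all[, 1], all[, 2], role = "target",
                      structure_id = all[, 3], structure_kind = "npc",
                      fov = fov)
  })
}

#' Ground-truth layout of molecule-filled vesicles plus calibration sites
#'
#' Vesicles are discs of the given diameter (default 300 nm, the scale of
#' Collagen-IV transport vesicles) filled with sites drawn uniformly over
#' the disc. In addition, isolated single-site calibration structures are
#' placed at least three vesicle diameters away from any vesicle; their
#' dark-time kinetics calibrate the qPAINT unit index.
#'
#' @param n_vesicles number of vesicles.
#' @param molecules_per_vesicle either a single positive integer (fixed
#'   count per vesicle) or a function `f(n)` returning `n` positive
#'   integer counts.
#' @param diameter vesicle diameter in nm.
#' @param n_calibration_singles number of isolated single-site structures.
#' @inheritParams make_origami_layout
#' @return An `emitter_model` with kinds `"vesicle"` and `"isolated"`;
#'   calibration sites carry role `"calibration_single"`.
#' @export
make_vesicle_layout <- function(n_vesicles, molecules_per_vesicle = 46,
                                diameter = 300, n_calibration_singles = 0,
                                fov = c(20000, 20000), seed = 1L) {
  if (!is_count(n_vesicles) || !is_count(n_calibration_singles))
    stop_arg("counts must be non-negative integers")
  if (!is_pos_num(diameter)) stop_arg("diameter must be positive")
  if (n_vesicles == 0 && n_calibration_singles == 0)
    return(new_emitter_model(numeric(0), numeric(0), fov = fov,
                             structure_kind = character(0), role = character(0),
                             structure_id = integer(0)))
  with_seed_(seed, {
    counts <- if (is.function(molecules_per_vesicle)) {
      as.integer(molecules_per_vesicle(n_vesicles))
    } else {
      rep_len(as.integer(molecules_per_vesicle), n_vesicles)
    }
    if (n_vesicles > 0 && any(counts < 1))
      stop_arg("molecules_per_vesicle must draw positive integers")
    R <- diameter / 2
    vc <- place_centers_(n_vesicles, fov, min_sep = 2 * diameter, margin = R + 1)
    pieces <- lapply(seq_len(n_vesicles), function(i) {
      k <- counts[i]
      r <- R * sqrt(runif(k)); th <- runif(k, 0, 2 * pi)
      cbind(vc[i, 1] + r * cos(th), vc[i, 2] + r * sin(th), i - 1L)
    })
    ves <- if (n_vesicles > 0) do.call(rbind, pieces) else matrix(numeric(0), ncol = 3)
    # calibration singles: >= 3 diameters from every vesicle center (edge
    # distance > 2.5 diameters), mutually separated by >= 1 um so each is
    # an isolated cluster for qPAINT unit-index calibration
    sx <- numeric(0); sy <- numeric(0); tries <- 0L
    while (length(sx) < n_calibration_singles) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop_arg("placement error: could not place %d calibration sites away from vesicles",
                 n_calibration_singles)
      px <- runif(1, 1, fov[1] - 1); py <- runif(1, 1, fov[2] - 1)
      ok_v <- n_vesicles == 0 ||
        all((px - vc[, 1])^2 + (py - vc[, 2])^2 >= (3 * diameter)^2)
      ok_s <- length(sx) == 0 || all((px - sx)^2 + (py - sy)^2 >= 1000^2)
      if (ok_v && ok_s) { sx <- c(sx, px); sy <- c(sy, py) }
    }
    x <- c(ves[, 1], sx); y <- c(ves[, 2], sy)
    sid <- c(ves[, 3], if (n_calibration_singles) n_vesicles + seq_len(n_calibration_singles) - 1L)
    role <- c(rep("target", nrow(ves)), rep("calibration_single", n_calibration_singles))
    kind <- c(rep("vesicle", nrow(ves)), rep("isolated", n_calibration_singles))
    new_emitter_model(x, y, role = role, structure_id = sid,
                      structure_kind = kind, fov = fov)
  })
}

#' Add always-bright fiducial markers to an emitter layout
#'
#' Fiducials emulate gold nanoparticles: they are localized in every frame
#' with a high photon count and anchor drift estimation.
#'
#' @param model an `emitter_model`.
#' @param n number of fiducials.
#' @param seed integer seed.
#' @return The model with `n` extra sites of role `"fiducial"`.
#' @export
add_fiducials <- function(model, n, seed = 1L) {
  validate_emitter_model(model)
  if (!is_count(n)) stop_arg("n must be a non-negative integer")
  if (n == 0) return(model)
  fov <- attr(model, "fov")
  if (is.null(fov)) stop_arg("model carries no field of view")
  with_seed_(seed, {
    ctr <- place_centers_(n, fov, min_sep = 500, margin = 10)
    base <- if (nrow(model)) max(model$structure_id) + 1L else 0L
    add <- new_emitter_model(ctr[, 1], ctr[, 2], role = "fiducial",
                             structure_id = base + seq_len(n) - 1L,
                             structure_kind = "fiducial", fov = fov)
    out <- rbind(as.data.frame(model), as.data.frame(add))
    attr(out, "fov") <- fov
    class(out) <- c("emitter_model", "data.frame")
    out
  })
}
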