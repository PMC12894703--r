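## Seeded generators for ground-truth-labeled synthetic particle lists and
## the noise-corruption model, so every pipeline is testable at desk scale
## without downloads.

#' Noise model for synthetic particle lists
#'
#' Positional noise adds an isotropic Gaussian displacement with per-axis
#' standard deviation \code{0.8 * positional_level / 3} nm, so that the
#' effective (3 sigma) displacement bound is about 0.8 nm at level 1 and
#' 4 nm at level 5. Orientational noise adds \code{level * N} (N a matrix
#' of independent standard normals) to each rotation matrix and projects
#' back to the nearest rotation by SVD; levels up to 1 produce angular
#' deviations up to roughly 60 degrees.
#'
#' @param positional_level positional noise level (>= 0).
#' @param orientational_level orientational noise level in [0, 1]
#'   typically; any value >= 0 is accepted.
#' @param seed integer seed making the corruption reproducible.
#' @return an object of class \code{"NoiseModel"}.
#' @export
noiseModel <- function(positional_level = 0, orientational_level = 0,
                       seed = 1L) {
  stopifnot(positional_level >= 0, orientational_level >= 0)
  structure(list(positional_level = positional_level,
                 orientational_level = orientational_level,
                 seed = as.integer(seed)),
            class = "NoiseModel")
}

#' Corrupt a particle list with positional and orientational noise
#'
#' Reproducible given the noise model's seed; with both levels at zero the
#' input is returned unchanged. Corrupted rotations always satisfy the
#' rotation invariants (SVD projection).
#'
#' @param pl a \code{\link{ParticleList}}.
#' @param noise a \code{\link{noiseModel}}.
#' @return the corrupted \code{ParticleList}.
#' @export
corruptParticles <- function(pl, noise) {
  stopifnot(inherits(noise, "NoiseModel"))
  if (noise$positional_level == 0 && noise$orientational_level == 0)
    return(pl)
  n <- nParticles(pl)
  .withSeed(noise$seed, {
    if (noise$orientational_level > 0) {
      lam <- noise$orientational_level
      for (k in seq_len(n)) {
        N <- matrix(stats::rnorm(9), 3, 3)
        pl@rotation[, , k] <- projectToSO3(pl@rotation[, , k] + lam * N)
      }
    }
    if (noise$positional_level > 0) {
      sigma <- 0.8 * noise$positional_level / 3
      pl@position <- pl@position +
        matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
    }
  })
  validObject(pl)
  pl
}

#' Generate a planar triangular lattice of oriented particles
#'
#' Vertices of a regular triangular (hexagonally coordinated) lattice in
#' the z = 0 plane: each interior vertex has six first-shell neighbors at
#' the lattice spacing. Orientations are in-plane rotations about +z drawn
#' from the chosen sampler; \code{"c_n_multiples"} draws uniformly from
#' the n multiples of 360/n degrees, emulating a lattice of Cn-symmetric
#' particles whose stored orientations are ambiguous modulo the symmetry.
#'
#' @param shells number of hexagonal rings around the center (>= 1);
#'   \code{shells = 1} gives 7 particles.
#' @param spacing lattice constant in nm.
#' @param orientation_sampler \code{"c_n_multiples"}, \code{"identity"} or
#'   \code{"random"} (uniform in-plane angle).
#' @param n_fold fold order for \code{"c_n_multiples"} (default 6).
#' @param seed RNG seed for the samplers.
#' @return a \code{\link{ParticleList}} (class label "lattice").
#' @export
generatePlanarLattice <- function(shells, spacing = 10,
                                  orientation_sampler = c("c_n_multiples",
                                                          "identity",
                                                          "random"),
                                  n_fold = 6L, seed = 1L) {
  stopifnot(shells >= 1, spacing > 0)
  orientation_sampler <- match.arg(orientation_sampler)
  ij <- expand.grid(i = -shells:shells, j = -shells:shells)
  hexd <- (abs(ij$i) + abs(ij$j) + abs(ij$i + ij$j)) / 2
  ij <- ij[hexd <= shells, , drop = FALSE]
  pos <- cbind(spacing * (ij$i + ij$j / 2),
               spacing * ij$j * sqrt(3) / 2,
               0)
  n <- nrow(pos)
  angles <- .withSeed(seed, switch(orientation_sampler,
    c_n_multiples = (360 / n_fold) * sample.int(n_fold, n,
                                                replace = TRUE) - 360 /
      n_fold,
    identity = rep(0, n),
    random = stats::runif(n, 0, 360)))
  rot <- array(0, c(3, 3, n))
  for (k in seq_len(n)) rot[, , k] <- rotZ(angles[k])
  particleList(pos, rot, class_label = "lattice", unit = "nm",
               provenance = list(generator = "planar_lattice",
                                 shells = shells, spacing = spacing,
                                 sampler = orientation_sampler,
                                 n_fold = n_fold, seed = seed))
}

#' Generate a ring assembly of subunits
#'
#' n subunits equally spaced on a circle in the z = 0 plane, each oriented
#' with its intrinsic -x axis pointing at the ring center and intrinsic z
#' along the ring axis, so consecutive subunits differ by an in-plane
#' rotation of 360/n degrees (45 degrees for the eightfold ring geometry
#' of a nuclear pore complex). Shifting the subunits along their intrinsic
#' -x axes by the ring radius collapses them onto the center.
#'
#' @param n_subunits number of subunits (>= 3).
#' @param radius ring radius in nm.
#' @param tomo_id,object_id identifiers for the generated ring.
#' @param center ring center (3-vector, default origin).
#' @param jitter optional \code{\link{noiseModel}} applied to the ideal
#'   ring.
#' @return a \code{\link{ParticleList}} (class label "ring").
#' @export
generateRing <- function(n_subunits, radius, tomo_id = 1L, object_id = 0L,
                         center = c(0, 0, 0), jitter = NULL) {
  stopifnot(n_subunits >= 3, radius > 0)
  phi <- 360 * (seq_len(n_subunits) - 1) / n_subunits
  pos <- cbind(radius * cos(radians(phi)), radius * sin(radians(phi)), 0)
  pos <- sweep(pos, 2, center, "+")
  rot <- array(0, c(3, 3, n_subunits))
  for (k in seq_len(n_subunits)) rot[, , k] <- rotZ(phi[k])
  pl <- particleList(pos, rot, tomo_id = tomo_id, object_id = object_id,
                     class_label = "ring", unit = "nm",
                     provenance = list(generator = "ring",
                                       n_subunits = n_subunits,
                                       radius = radius))
  if (!is.null(jitter)) pl <- corruptParticles(pl, jitter)
  pl
}

#' Specification of a synthetic chromatin-like scene
#'
#' Building blocks mirror the nucleosome arrangements seen in chromatin:
#' stacked pairs (partner displaced by \code{stack_translation} along the
#' intrinsic +y stacking axis and twisted by \code{stack_twist} about it),
#' trinucleosomes (a stacked pair plus a third, linker-connected particle
#' at \code{linker_distance} whose relative rotation of
#' \code{linker_twist} degrees is about \code{linker_axis}, with the
#' displacement tilted \code{linker_tilt} degrees off the intrinsic +z DNA
#' entry/exit direction), and 12-particle helices built from six stacked
#' pairs propagated along the discrete screw motion of the linker, with
#' exactly one pair's stack twist inflated by
#' \code{stack_twist_wide_factor}. Mononucleosomes fill the box uniformly
#' at random.
#'
#' @param n_helix,n_stack,n_tri,n_mono block counts (defaults 6, 350, 340,
#'   3200).
#' @param box scene extent in nm (3-vector).
#' @param min_separation minimum distance between particles of different
#'   blocks (rejection sampling; nm).
#' @param stack_translation,stack_twist stack geometry (nm, degrees).
#' @param stack_twist_wide_factor inflation factor of the one widened pair
#'   per helix.
#' @param linker_distance,linker_twist,linker_axis,linker_tilt dinucleosome
#'   linker geometry (nm, degrees, unit vector, degrees).
#' @param wide_pair_index which of the six helix pairs is widened.
#' @param max_attempts placement attempts per block before giving up.
#' @return a list of class \code{"ChromatinSpec"}.
#' @export
chromatinSpec <- function(n_helix = 6L, n_stack = 350L, n_tri = 340L,
                          n_mono = 3200L, box = c(400, 400, 120),
                          min_separation = 6,
                          stack_translation = 6, stack_twist = 15,
                          stack_twist_wide_factor = 3,
                          linker_distance = 24.5, linker_twist = 36,
                          linker_axis = c(0, 0, 1), linker_tilt = 2,
                          wide_pair_index = 3L, max_attempts = 5000L) {
  stopifnot(n_helix >= 0, n_stack >= 0, n_tri >= 0, n_mono >= 0,
            min_separation > 0, length(box) == 3L, all(box > 0),
            stack_twist_wide_factor > 1,
            wide_pair_index >= 1L, wide_pair_index <= 6L)
  structure(list(n_helix = n_helix, n_stack = n_stack, n_tri = n_tri,
                 n_mono = n_mono, box = as.numeric(box),
                 min_separation = min_separation,
                 stack_translation = stack_translation,
                 stack_twist = stack_twist,
                 stack_twist_wide_factor = stack_twist_wide_factor,
                 linker_distance = linker_distance,
                 linker_twist = linker_twist,
                 linker_axis = .unitize(linker_axis, "linker_axis"),
                 linker_tilt = linker_tilt,
                 wide_pair_index = as.integer(wide_pair_index),
                 max_attempts = as.integer(max_attempts)),
            class = "ChromatinSpec")
}

## local-frame building blocks: lists of (rotation, position) rows
.stackMotion <- function(spec, wide = FALSE) {
  tw <- spec$stack_twist * if (wide) spec$stack_twist_wide_factor else 1
  list(rot = rotY(tw), t = c(0, spec$stack_translation, 0))
}

.linkerMotion <- function(spec) {
  u <- c(sin(radians(spec$linker_tilt)), 0, cos(radians(spec$linker_tilt)))
  list(rot = rotAxis(spec$linker_axis, spec$linker_twist),
       t = spec$linker_distance * u)
}

## compose local poses: given pose (R, p) and motion (r, t) return
## (R r, p + R t)
.chain <- function(pose, mot) {
  list(rot = pose$rot %*% mot$rot,
       p = pose$p + as.numeric(pose$rot %*% mot$t))
}

## block builders return list(pos = m x 3, rot = 3x3xm, stacked_pairs =
## 2-col matrix of local indices, wide_pairs = same)
.blockStack <- function(spec) {
  a <- list(rot = diag(3), p = c(0, 0, 0))
  b <- .chain(a, .stackMotion(spec))
  list(pos = rbind(a$p, b$p), rot = array(c(a$rot, b$rot), c(3, 3, 2)),
       stacked_pairs = rbind(c(1L, 2L)), wide_pairs = NULL)
}

.blockTri <- function(spec) {
  a <- list(rot = diag(3), p = c(0, 0, 0))
  b <- .chain(a, .stackMotion(spec))
  c_ <- .chain(a, .linkerMotion(spec))
  list(pos = rbind(a$p, b$p, c_$p),
       rot = array(c(a$rot, b$rot, c_$rot), c(3, 3, 3)),
       stacked_pairs = rbind(c(1L, 2L)), wide_pairs = NULL)
}

.blockHelix <- function(spec) {
  L <- .linkerMotion(spec)
  base <- list(rot = diag(3), p = c(0, 0, 0))
  pos <- matrix(0, 12, 3)
  rot <- array(0, c(3, 3, 12))
  sp <- NULL; wp <- NULL
  for (k in 1:6) {
    wide <- k == spec$wide_pair_index
    top <- .chain(base, .stackMotion(spec))
    pos[2 * k - 1, ] <- base$p
    ## the widened pair gets its extra stack twist by counter-twisting the
    ## bottom particle about the stacking axis: the pair's angular distance
    ## becomes wide_factor * stack_twist while both particles keep their
    ## places on the two strands of the double helix
    rot[, , 2 * k - 1] <- if (wide)
      base$rot %*% rotY(-(spec$stack_twist_wide_factor - 1) *
                          spec$stack_twist)
    else base$rot
    pos[2 * k, ] <- top$p; rot[, , 2 * k] <- top$rot
    if (wide) wp <- rbind(wp, c(2L * k - 1L, 2L * k))
    else sp <- rbind(sp, c(2L * k - 1L, 2L * k))
    base <- .chain(base, L)
  }
  list(pos = pos, rot = rot, stacked_pairs = sp, wide_pairs = wp)
}

#' Generate a synthetic chromatin-like particle list
#'
#' Instantiates the blocks of a \code{\link{chromatinSpec}}: each block is
#' given a uniform random global rotation and a uniform random position in
#' the box, re-drawn until all of its particles keep
#' \code{min_separation} to every previously placed particle, then
#' mononucleosomes with uniform random positions and orientations are
#' added the same way. Class labels are "helix", "stack", "tri", "mono";
#' each block gets an object id; the provenance records the intended
#' (non-widened) stacked pairs and the widened pairs so that classifier
#' recall is computable without ambiguity. Pure function of (spec, seed).
#'
#' @param spec a \code{\link{chromatinSpec}}.
#' @param seed integer seed.
#' @return a \code{\link{ParticleList}} in nm.
#' @export
generateChromatin <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ChromatinSpec"))
  .withSeed(seed, {
    ntot <- spec$n_helix * 12L + spec$n_stack * 2L + spec$n_tri * 3L +
      spec$n_mono
    pos <- matrix(NA_real_, ntot, 3)
    rot <- array(NA_real_, c(3, 3, ntot))
    lab <- character(ntot)
    oid <- rep(NA_integer_, ntot)
    filled <- 0L
    object_counter <- 0L
    stacked_pairs <- NULL
    wide_pairs <- NULL
    minsep2 <- spec$min_separation^2
    placeBlock <- function(block, label) {
      m <- nrow(block$pos)
      for (attempt in seq_len(spec$max_attempts)) {
        R <- randomRotations(1)[, , 1]
        ctr <- stats::runif(3) * spec$box
        cand <- block$pos %*% t(R) + matrix(ctr, m, 3, byrow = TRUE)
        if (any(cand < 0) || any(cand > matrix(spec$box, m, 3,
                                               byrow = TRUE))) next
        if (filled > 0L) {
          prev <- pos[seq_len(filled), , drop = FALSE]
          d2 <- outer(rowSums(cand^2), rowSums(prev^2), "+") -
            2 * cand %*% t(prev)
          if (any(d2 < minsep2)) next
        }
        idx <- filled + seq_len(m)
        pos[idx, ] <<- cand
        for (k in seq_len(m)) rot[, , idx[k]] <<- R %*% block$rot[, , k]
        lab[idx] <<- label
        oid[idx] <<- object_counter
        if (!is.null(block$stacked_pairs))
          stacked_pairs <<- rbind(stacked_pairs,
                                  matrix(idx[block$stacked_pairs],
                                         ncol = 2))
        if (!is.null(block$wide_pairs))
          wide_pairs <<- rbind(wide_pairs,
                               matrix(idx[block$wide_pairs], ncol = 2))
        object_counter <<- object_counter + 1L
        filled <<- filled + m
        return(invisible(TRUE))
      }
      stop("could not place a '", label, "' block after ",
           spec$max_attempts, " attempts; use a larger box or smaller ",
           "min_separation")
    }
    for (b in seq_len(spec$n_helix)) placeBlock(.blockHelix(spec), "helix")
    for (b in seq_len(spec$n_stack)) placeBlock(.blockStack(spec), "stack")
    for (b in seq_len(spec$n_tri)) placeBlock(.blockTri(spec), "tri")
    if (spec$n_mono > 0L) {
      mono <- list(pos = matrix(0, 1, 3),
                   rot = array(diag(3), c(3, 3, 1)),
                   stacked_pairs = NULL, wide_pairs = NULL)
      for (b in seq_len(spec$n_mono)) {
        mono$rot[, , 1] <- diag(3)  # block rotation supplies orientation
        placeBlock(mono, "mono")
      }
      oid[lab == "mono"] <- NA_integer_
    }
    particleList(pos, rot, object_id = oid, class_label = lab,
                 unit = "nm",
                 provenance = list(generator = "chromatin", spec = spec,
                                   seed = seed,
                                   stacked_pairs = stacked_pairs,
                                   wide_pairs = wide_pairs))
  })
}
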