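# Coordinate-model handling and the geometry metrics used to describe the
# hexamer spiral-to-ring transition: rigid superposition, domain centroids,
# inter-domain distances/angles, per-subunit rise, inter-subunit gaps and
# the pore-radius profile.

#' Construct a structure model
#'
#' A flat atom table in Angstrom with chain/residue bookkeeping; the common
#' currency of all geometry operations.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `elesy` (element symbol), `x`, `y`, `z` (Angstrom).
#' @param source free-text identifier of the model's origin.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "unknown") {
  need <- c("chain", "resno", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  stop_if(length(miss) > 0, "atom table lacks column(s): %s",
          paste(miss, collapse = ", "))
  stop_if(!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)),
          "non-finite coordinates in atom table")
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d atoms, chains %s\n", x$source,
              nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = "")))
  invisible(x)
}

#' Read a PDB or mmCIF coordinate file
#'
#' All ATOM/HETATM records are loaded; chain and author residue numbering
#' are preserved and gaps are kept as gaps (no interpolation).
#'
#' @param path file path ending in `.pdb`, `.ent`, or `.cif`.
#' @return A [structure_model()].
#' @export
read_structure <- function(path) {
  stop_if(!file.exists(path), "no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    switch(ext,
           cif = bio3d::read.cif(path),
           pdb = , ent = bio3d::read.pdb(path),
           stop_if(TRUE, "unsupported structure format '.%s' (use PDB or mmCIF)", ext)),
    error = function(e) stop_if(TRUE, "failed to parse %s: %s", path,
                                conditionMessage(e)))
  a <- pdb$atom
  structure_model(data.frame(chain = a$chain, resno = a$resno,
                             resid = a$resid, elety = a$elety,
                             elesy = a$elesy %||% substr(a$elety, 1, 1),
                             x = a$x, y = a$y, z = a$z,
                             stringsAsFactors = FALSE),
                  source = basename(path))
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, eleno = seq_len(nrow(a)),
                   elesy = a$elesy)
  invisible(path)
}

#' Generate a toy hexamer coordinate model with known geometry
#'
#' Lobe centroids sit at equal angular spacing on a circle of
#' `ring_radius`, with axial positions in arithmetic progression of step
#' `rise_per_subunit` (0 = planar ring). Atom clouds are centro-symmetric
#' about each centroid so the per-chain centroid is exact. A synthetic
#' fixture for the pseudo-AFM simulator and the geometry metrics, not a
#' protein model; spec dimensions are nm, the emitted coordinates Angstrom.
#'
#' @param spec a [toy_hexamer_spec()] object.
#' @param path optional output PDB path; if given, the model is written.
#' @return list with `model` (a [structure_model()], coordinates in
#'   Angstrom), `truth` (data.frame of exact per-chain centroids, Angstrom,
#'   and rise), and `path` (or NA).
#' @export
make_toy_hexamer <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toy_hexamer_spec"))
  set.seed(spec$seed)
  n <- spec$n_subunits
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cent <- cbind(x = 10 * spec$ring_radius * cos(ang),
                y = 10 * spec$ring_radius * sin(ang),
                z = 10 * spec$rise_per_subunit * (seq_len(n) - 1L))
  half <- spec$atoms_per_lobe / 2L
  rows <- list()
  for (k in seq_len(n)) {
    # uniform draws in the lobe sphere, mirrored for an exact centroid
    off <- matrix(stats::runif(3 * half, -1, 1), ncol = 3)
    off <- off / pmax(sqrt(rowSums(off^2)), 1) *
      (stats::runif(half)^(1 / 3) * 10 * spec$lobe_radius)
    off <- rbind(off, -off)
    rows[[k]] <- data.frame(chain = LETTERS[k],
                            resno = seq_len(nrow(off)), resid = "ALA",
                            elety = "CA", elesy = "C",
                            x = cent[k, 1] + off[, 1],
                            y = cent[k, 2] + off[, 2],
                            z = cent[k, 3] + off[, 3],
                            stringsAsFactors = FALSE)
  }
  model <- structure_model(do.call(rbind, rows), source = "toy_hexamer")
  truth <- data.frame(chain = LETTERS[seq_len(n)], cx = cent[, 1],
                      cy = cent[, 2], cz = cent[, 3],
                      ring_radius = 10 * spec$ring_radius,
                      rise_step = 10 * spec$rise_per_subunit)
  if (!is.null(path)) write_structure(model, path)
  list(model = model, truth = truth, path = path %||% NA_character_)
}

# -- superposition ----------------------------------------------------------

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Pairs atoms of `mobile` and `reference` by (chain, residue number, atom
#' name) within `selection`, then solves the orthogonal-Procrustes problem
#' by singular value decomposition with the usual determinant correction to
#' exclude reflections.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param selection optional list with any of `chain`, `resno`, `elety`
#'   (vectors of allowed values) restricting the paired atoms; default pairs
#'   all shared atoms.
#' @return list of class `superposition`: `rotation` (3x3), `translation`
#'   (length 3; maps mobile as `x R + t`), `rmsd` (Angstrom), `n_atoms`,
#'   and `transform(model)` applying the fit to a full model.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"))
  key <- function(a) paste(a$chain, a$resno, a$elety, sep = "|")
  sel_rows <- function(a) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
    if (!is.null(selection$resno)) keep <- keep & a$resno %in% selection$resno
    if (!is.null(selection$elety)) keep <- keep & a$elety %in% selection$elety
    a[keep, , drop = FALSE]
  }
  am <- sel_rows(mobile$atoms); ar <- sel_rows(reference$atoms)
  km <- key(am); kr <- key(ar)
  common <- intersect(km, kr)
  stop_if(length(common) < 3L,
          "superposition needs >= 3 paired atoms, found %d", length(common))
  X <- as.matrix(am[match(common, km), c("x", "y", "z")])
  Y <- as.matrix(ar[match(common, kr), c("x", "y", "z")])
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  s <- svd(crossprod(Xc, Yc))           # X^T Y
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- my - as.numeric(mx %*% R)
  fitted <- Xc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  out <- list(rotation = R, translation = t_vec, rmsd = rmsd,
              n_atoms = length(common))
  out$transform <- function(model) {
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
    xyz <- sweep(xyz, 2, t_vec, `+`)
    model$atoms[, c("x", "y", "z")] <- xyz
    model
  }
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d paired atoms, RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

# -- domain metrics ---------------------------------------------------------

#' Define named domains by residue ranges
#'
#' @param ... named arguments, each a length-2 numeric `c(first, last)`
#'   residue range (inclusive, author numbering).
#' @return An object of class `domain_definition`.
#' @export
domain_definition <- function(...) {
  doms <- list(...)
  stop_if(length(doms) == 0 || is.null(names(doms)) || any(names(doms) == ""),
          "domains must be named residue ranges")
  for (nm in names(doms)) {
    r <- doms[[nm]]
    stop_if(length(r) != 2 || r[1] > r[2],
            "domain '%s' must be c(first, last) with first <= last", nm)
  }
  rngs <- do.call(rbind, lapply(doms, function(r) sort(r)))
  o <- order(rngs[, 1])
  overlap <- any(rngs[o, 1][-1] <= rngs[o, 2][-nrow(rngs)])
  stop_if(overlap, "domain residue ranges overlap")
  structure(doms, class = "domain_definition")
}

#' Per-subunit domain centroids, inter-domain distance and angle
#'
#' For each chain: the unweighted mean of C-alpha coordinates in each domain
#' range; `d_NBD`, the distance between the first and second NBD centroids;
#' and `theta_HBD`, the angle (degrees) at the HBD centroid subtended by
#' vectors to the two NBD centroids. Deltas are reported relative to a
#' reference chain.
#'
#' @param model a [structure_model()].
#' @param domains a [domain_definition()]; the distance uses domains named
#'   in `nbd_pair` and the angle the vertex in `hbd`.
#' @param ref_chain chain against which deltas are reported (default "A").
#' @param nbd_pair names of the two NBD domains.
#' @param hbd name of the angle-vertex domain (NULL skips the angle).
#' @param atom_name atom used for centroids (default C-alpha).
#' @return data.frame of class `subunit_metrics`: one row per chain with
#'   centroid columns, `d_NBD`, `theta_HBD`, `delta_d_NBD`, `delta_theta`.
#' @export
subunit_metrics <- function(model, domains, ref_chain = "A",
                            nbd_pair = c("AAA1_NBD", "AAA2_NBD"),
                            hbd = "AAA2_HBD", atom_name = "CA") {
  stopifnot(inherits(model, "structure_model"),
            inherits(domains, "domain_definition"))
  a <- model$atoms[model$atoms$elety == atom_name, , drop = FALSE]
  chains <- sort(unique(model$atoms$chain))
  stop_if(!ref_chain %in% chains, "reference chain '%s' absent", ref_chain)
  cent <- function(ch, dom) {
    r <- domains[[dom]]
    sel <- a$chain == ch & a$resno >= r[1] & a$resno <= r[2]
    stop_if(sum(sel) < 3,
            "domain '%s' resolves to %d residue(s) in chain %s (need >= 3)",
            dom, sum(sel), ch)
    colMeans(as.matrix(a[sel, c("x", "y", "z")]))
  }
  rows <- lapply(chains, function(ch) {
    c1 <- cent(ch, nbd_pair[1]); c2 <- cent(ch, nbd_pair[2])
    d <- sqrt(sum((c1 - c2)^2))
    th <- NA_real_
    if (!is.null(hbd) && hbd %in% names(domains)) {
      ch_ <- cent(ch, hbd)
      v1 <- c1 - ch_; v2 <- c2 - ch_
      cs <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      th <- acos(pmin(pmax(cs, -1), 1)) * 180 / pi
    }
    data.frame(chain = ch, d_NBD = d, theta_HBD = th)
  })
  out <- do.call(rbind, rows)
  ref <- out[out$chain == ref_chain, ]
  out$delta_d_NBD <- out$d_NBD - ref$d_NBD
  out$delta_theta <- out$theta_HBD - ref$theta_HBD
  class(out) <- c("subunit_metrics", "data.frame")
  attr(out, "ref_chain") <- ref_chain
  out
}

# -- whole-ring metrics -----------------------------------------------------

#' Ring-axis metrics: per-subunit rise, adjacent gaps, pore profile
#'
#' The ring axis is the normal of the least-squares plane through the chain
#' centroids (smallest principal component), centred at their mean and
#' oriented so rises increase with chain order. Rise is the axial projection
#' of each centroid; adjacent gap the minimal inter-chain atom distance for
#' consecutive chains; the pore profile, per axial slab, twice the minimum
#' over atoms of (axial-distance minus van der Waals radius).
#'
#' @param model a [structure_model()].
#' @param atom_name atom used for centroids/gaps (default "CA"; use NULL
#'   for all atoms).
#' @param slab_width axial slab thickness for the pore profile (Angstrom).
#' @param radii optional per-atom radii (Angstrom); default element table.
#' @return list of class `ring_metrics`: `axis`, `centre`, `rise` (named
#'   per chain), `adjacent_gap`, `pore_profile` (data.frame z, diameter),
#'   `pore_diameter` (minimum over the profile's central half).
#' @export
ring_metrics <- function(model, atom_name = "CA", slab_width = 4,
                         radii = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  sel <- if (is.null(atom_name)) rep(TRUE, nrow(a)) else a$elety == atom_name
  ac <- a[sel, , drop = FALSE]
  chains <- sort(unique(ac$chain))
  stop_if(length(chains) < 3, "ring metrics need >= 3 chains")
  cent <- t(vapply(chains, function(ch)
    colMeans(as.matrix(ac[ac$chain == ch, c("x", "y", "z")])), numeric(3)))
  centre <- colMeans(cent)
  cc <- sweep(cent, 2, centre)
  stop_if(qr(cc)$rank < 2, "degenerate centroid configuration")
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  axis <- ev$vectors[, 3]
  # the plane normal tilts for a spiral (a tilt absorbs the linear rise
  # trend); refine to the cylinder axis, which minimises the spread of the
  # centroids' radial distances and is tilt-free for a circular staircase
  rad_var <- function(sph) {
    u <- c(cos(sph[1]) * sin(sph[2]), sin(sph[1]) * sin(sph[2]), cos(sph[2]))
    ax_comp <- as.numeric(cc %*% u)
    stats::var(sqrt(pmax(rowSums(cc^2) - ax_comp^2, 0)))
  }
  sph0 <- c(atan2(axis[2], axis[1]), acos(pmin(pmax(axis[3], -1), 1)))
  opt <- stats::optim(sph0, rad_var, method = "Nelder-Mead",
                      control = list(reltol = 1e-12))
  axis <- c(cos(opt$par[1]) * sin(opt$par[2]),
            sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[2]))
  rise <- as.numeric(cc %*% axis)
  if (stats::sd(rise) > 1e-9 &&
      stats::cor(rise, seq_along(rise)) < 0) { axis <- -axis; rise <- -rise }
  names(rise) <- chains

  gap <- vapply(seq_along(chains), function(i) {
    j <- if (i == length(chains)) 1L else i + 1L
    xi <- as.matrix(ac[ac$chain == chains[i], c("x", "y", "z")])
    xj <- as.matrix(ac[ac$chain == chains[j], c("x", "y", "z")])
    min(sqrt(outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj)))
  }, numeric(1))
  names(gap) <- paste(chains, chains[c(seq_along(chains)[-1], 1L)], sep = "-")

  all_xyz <- sweep(as.matrix(a[, c("x", "y", "z")]), 2, centre)
  axial <- as.numeric(all_xyz %*% axis)
  radial <- sqrt(rowSums((all_xyz - outer(axial, axis))^2))
  r_atom <- radii %||% (10 * vdw_radius_nm(a$elesy))
  breaks <- seq(min(axial), max(axial) + slab_width, by = slab_width)
  slab <- findInterval(axial, breaks)
  prof <- vapply(seq_len(max(slab)), function(s) {
    idx <- slab == s
    if (!any(idx)) return(NA_real_)
    2 * max(min(radial[idx] - r_atom[idx]), 0)
  }, numeric(1))
  pore <- data.frame(z = breaks[seq_len(max(slab))] + slab_width / 2,
                     diameter = prof)
  core <- pore$diameter[pore$z > stats::quantile(axial, 0.25) &
                        pore$z < stats::quantile(axial, 0.75)]
  structure(list(axis = axis, centre = centre, rise = rise,
                 adjacent_gap = gap, pore_profile = pore,
                 pore_diameter = if (length(core)) min(core, na.rm = TRUE)
                                 else min(pore$diameter, na.rm = TRUE)),
            class = "ring_metrics")
}

#' @export
print.ring_metrics <- function(x, ...) {
  cat("Ring metrics\n")
  cat("  rise (A):", paste(sprintf("%s %.2f", names(x$rise), x$rise),
                           collapse = ", "), "\n")
  cat(sprintf("  pore diameter (A): %.2f\n", x$pore_diameter))
  invisible(x)
}
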