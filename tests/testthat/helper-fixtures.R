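# Fixtures built in code at test time.

# A synthetic hexamer with three named pseudo-domains per chain whose
# inter-domain distance d(NBD1, NBD2) and angle at the HBD centroid are
# planted exactly per chain. Synthetic stand-in geometry: it validates the
# measurement pipeline, not any deposited model.
make_synthetic_spiral_hexamer <- function(d_by_chain, theta_by_chain,
                                          l1 = 25, ring_radius = 60,
                                          rise = 8, atoms_per_domain = 8,
                                          seed = 1) {
  set.seed(seed)
  chains <- names(d_by_chain)
  rows <- list()
  for (k in seq_along(chains)) {
    th <- theta_by_chain[k] * pi / 180
    d <- d_by_chain[k]
    # HBD at the vertex; NBD1 at distance l1; NBD2 at distance l2 such
    # that the planted distance d is realised at the planted angle
    l2 <- l1 * cos(th) + sqrt(d^2 - l1^2 * sin(th)^2)
    ang <- 2 * pi * (k - 1) / length(chains)
    # local in-plane frame rotated per chain, plus axial rise
    e1 <- c(cos(ang), sin(ang), 0)
    e2 <- c(-sin(ang), cos(ang), 0)
    p_hbd <- ring_radius * e1 + c(0, 0, rise * (k - 1))
    p_n1 <- p_hbd + l1 * e2
    p_n2 <- p_hbd + l2 * (cos(th) * e2 + sin(th) * c(0, 0, 1))
    mk <- function(centre, res0) {
      off <- matrix(stats::runif(3 * atoms_per_domain / 2, -2, 2), ncol = 3)
      off <- rbind(off, -off)   # centro-symmetric: exact centroid
      data.frame(chain = chains[k], resno = res0 + seq_len(nrow(off)),
                 resid = "ALA", elety = "CA", elesy = "C",
                 x = centre[1] + off[, 1], y = centre[2] + off[, 2],
                 z = centre[3] + off[, 3], stringsAsFactors = FALSE)
    }
    rows[[k]] <- rbind(mk(p_n1, 0), mk(p_n2, 100), mk(p_hbd, 200))
  }
  structure_model(do.call(rbind, rows), source = "synthetic_spiral_hexamer")
}

synthetic_hexamer_domains <- function(atoms_per_domain = 8) {
  domain_definition(AAA1_NBD = c(1, atoms_per_domain),
                    AAA2_NBD = c(101, 100 + atoms_per_domain),
                    AAA2_HBD = c(201, 200 + atoms_per_domain))
}

# Build a ring_state_series from a plain logical open/closed vector.
series_from_logical <- function(open, frame_rate = 5, subunit = 1L) {
  ring_state_series(lapply(open, function(o)
    if (is.na(o)) NA_integer_ else if (o) subunit else integer(0)),
    frame_rate)
}

# A series whose opening events are the given subunit sequence, one
# closed frame between consecutive openings.
series_from_events <- function(events, frame_rate = 5) {
  open_sets <- list()
  for (e in events) {
    open_sets <- c(open_sets, list(integer(0)), list(as.integer(e)))
  }
  open_sets <- c(open_sets, list(integer(0)))
  ring_state_series(open_sets, frame_rate)
}
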