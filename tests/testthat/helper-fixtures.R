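## Shared fixtures: toy references, small simulations, PDB writers,
## independent geometric oracles.

toy_reference <- function(length = 30, ptp_start = NULL, ptp_length = 10,
                          seed = 42) {
  synthetic_reference(length, ptp_start = ptp_start, ptp_length = ptp_length,
                      name = "toy", seed = seed)
}

## Independent brute-force oracle for single-nucleotide accessibility:
## builds the 9 neighbor codons by explicit string surgery and translates
## them with a locally constructed codon table.
accessible_oracle <- function(codon) {
  gc_tab <- as.list(Biostrings::GENETIC_CODE)
  hits <- character(0)
  for (i in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, i, i) == b) next
      neigh <- codon
      substr(neigh, i, i) <- b
      hits <- c(hits, gc_tab[[neigh]])
    }
  }
  sort(setdiff(unique(hits), gc_tab[[codon]]))
}

## ---- geometry -------------------------------------------------------

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Independent dihedral oracle: project the outer bonds onto the plane
## perpendicular to the central bond, take the angle between the
## projections, sign from the central-bond axis.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2 <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  w <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  cosphi <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  cosphi <- max(-1, min(1, cosphi))
  ang <- acos(cosphi) * 180 / pi
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  if (sum(b2 * cr) < 0) ang <- -ang
  ang
}

## Random single-frame "structure" with n atoms in generic residues.
random_frame <- function(n = 8) {
  data.frame(chain = "A", resno = seq_len(n), insert = "",
             resid = "GLY", elety = "X",
             x = stats::rnorm(n, sd = 5), y = stats::rnorm(n, sd = 5),
             z = stats::rnorm(n, sd = 5), stringsAsFactors = FALSE)
}

transform_frame <- function(frame, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(frame[c("x", "y", "z")]) %*% t(rot)
  frame$x <- xyz[, 1] + shift[1]
  frame$y <- xyz[, 2] + shift[2]
  frame$z <- xyz[, 3] + shift[3]
  frame
}

## ---- PDB writing ----------------------------------------------------

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, altloc = " ") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, altloc, resid, chain, resno, " ", x, y, z, occ, b,
          substr(name, 1, 1))
}

## frames: list of data.frames with chain, resno, resid, elety, x, y, z
## (and optionally occ, altloc). Writes multi-MODEL when > 1 frame.
write_test_pdb <- function(frames, path) {
  lines <- character(0)
  multi <- length(frames) > 1L
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (is.null(fr$occ)) fr$occ <- 1
    if (is.null(fr$altloc)) fr$altloc <- " "
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", f))
    for (i in seq_len(nrow(fr))) {
      lines <- c(lines, pdb_atom_line(i, fr$elety[i], fr$resid[i],
                                      fr$chain[i], fr$resno[i],
                                      fr$x[i], fr$y[i], fr$z[i],
                                      occ = fr$occ[i],
                                      altloc = fr$altloc[i]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## Synthetic SHP2-like fragment carrying every atom the built-in metric
## set needs, in 4DGP/6CRF residue numbering. Two frames: frame 1 is an
## open-like state (salt bridge formed, WPD open), frame 2 closed-like.
synthetic_shp2_fragment <- function() {
  mk <- function(resno, resid, elety, x, y, z) {
    data.frame(chain = "A", resno = resno, insert = "", resid = resid,
               elety = elety, x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  f1 <- rbind(
    mk(111, "ARG", "NH1", 0.0, 0.0, 0.0),
    mk(111, "ARG", "NH2", -1.2, 1.0, 0.3),
    mk(114, "HIS", "CA", 5.0, 2.0, 1.0),
    mk(216, "LEU", "O", 6.5, 4.0, 2.0),
    mk(218, "THR", "N", 8.0, 3.0, 0.0),
    mk(218, "THR", "CA", 9.4, 3.4, 0.4),
    mk(218, "THR", "C", 10.3, 2.3, 1.1),
    mk(219, "GLY", "N", 11.6, 2.6, 1.3),
    mk(249, "GLU", "OE1", 3.0, 0.5, 0.8),
    mk(249, "GLU", "OE2", 3.8, 1.6, 1.5),
    mk(250, "GLU", "OE1", 2.0, -2.5, 1.0),
    mk(250, "GLU", "OE2", 3.0, -3.5, 1.8),
    mk(423, "TRP", "CZ3", 20.0, 10.0, 5.0),
    mk(424, "PRO", "CG", 22.5, 11.0, 5.5),
    mk(425, "ASP", "CA", 24.0, 12.0, 6.0),
    mk(428, "VAL", "O", 23.5, 14.5, 7.0),
    mk(429, "PRO", "CG", 23.8, 9.5, 4.2),
    mk(459, "CYS", "CA", 32.0, 20.0, 11.0),
    mk(469, "PHE", "N", 18.0, 8.0, 3.0),
    mk(469, "PHE", "CA", 19.2, 8.8, 3.5),
    mk(469, "PHE", "CB", 20.1, 8.1, 4.5),
    mk(469, "PHE", "CG", 21.3, 8.9, 5.0)
  )
  ## Frame 2: break the salt bridge, close the WPD loop, rotate F469.
  f2 <- f1
  move <- function(fr, resno, elety, dx) {
    i <- fr$resno == resno & fr$elety == elety
    fr[i, c("x", "y", "z")] <- fr[i, c("x", "y", "z")] +
      matrix(dx, sum(i), 3, byrow = TRUE)
    fr
  }
  f2 <- move(f2, 249, "OE1", c(4, 3, 2))
  f2 <- move(f2, 249, "OE2", c(4, 3, 2))
  f2 <- move(f2, 250, "OE1", c(3, -4, 2))
  f2 <- move(f2, 250, "OE2", c(3, -4, 2))
  f2 <- move(f2, 459, "CA", c(-4, -4, -2.5))
  f2 <- move(f2, 469, "CG", c(-0.8, 1.2, 0.6))
  list(f1, f2)
}

## Small simulated dataset used across scoring tests.
small_sim <- function(length = 24, depth = 5e3, n_replicates = 3,
                      kinase = "cSrc_KD", seed = 7, exact = FALSE,
                      gt_seed = 11) {
  ref <- toy_reference(length = length, seed = 5)
  gt <- plant_landscape(ref, seed = gt_seed)
  cfg <- selection_config(kinase, depth_pre = depth, depth_post = depth,
                          n_replicates = n_replicates, seed = seed)
  sim <- simulate_selection(gt, ref, "FL", cfg, exact = exact)
  list(ref = ref, gt = gt, cfg = cfg, sim = sim)
}
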