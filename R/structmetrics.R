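## Geometric order parameters from PDB coordinates: distances, backbone
## psi and side-chain chi1 dihedrals, per frame, with optional state calls.

#' Read a PDB file into structure frames
#'
#' Parses a (possibly multi-MODEL) PDB via bio3d and returns one frame per
#' MODEL, in file order. Heteroatoms are ignored; where alternate
#' locations are present, the highest-occupancy altloc of each atom is
#' retained (first wins on ties). Residue numbering and insertion codes
#' are preserved verbatim.
#'
#' @param path PDB file path.
#' @return List of class `structure_frames`; each frame is a data.frame
#'   with columns `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`,
#'   `z`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  ## Highest-occupancy altloc per atom identity.
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  id <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (d in unique(id[duplicated(id)])) {
    rows <- which(id == d)
    best <- rows[which.max(at$o[rows])]
    keep[setdiff(rows, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  ## column triplets of the kept atoms within the original atom table
  orig_idx <- which(pdb$atom$type == "ATOM")[keep]
  cols <- as.vector(rbind(3L * orig_idx - 2L, 3L * orig_idx - 1L,
                          3L * orig_idx))
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    co <- matrix(xyz[f, cols], ncol = 3L, byrow = TRUE)
    data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
               resid = at$resid, elety = at$elety,
               x = co[, 1], y = co[, 2], z = co[, 3],
               stringsAsFactors = FALSE)
  })
  structure(frames, class = "structure_frames")
}

## Resolve atom selections; each selection is list(resno=, elety=, chain=NULL).
## Returns the coordinate matrix of matching atoms; errors name the miss.
resolve_atoms <- function(frame, resno, elety, chain = NULL) {
  sel <- frame$resno %in% resno & frame$elety %in% elety
  if (!is.null(chain)) sel <- sel & frame$chain %in% chain
  if (!any(sel)) {
    stop("no atom matches residue ", paste(resno, collapse = "/"),
         " atom ", paste(elety, collapse = "/"))
  }
  as.matrix(frame[sel, c("x", "y", "z")])
}

#' Distance between two atoms
#'
#' @param frame One frame from [read_structure()].
#' @param a,b Selections: `list(resno =, elety =, chain = NULL)`, each
#'   resolving to exactly one atom.
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(frame, a, b) {
  pa <- do.call(resolve_atoms, c(list(frame), a))
  pb <- do.call(resolve_atoms, c(list(frame), b))
  if (nrow(pa) != 1L || nrow(pb) != 1L) {
    stop("atom_distance selections must resolve to exactly one atom each")
  }
  sqrt(sum((pa[1, ] - pb[1, ])^2))
}

#' Shortest distance between two atom sets
#'
#' Minimum Euclidean distance over the cross product of the two selection
#' sets - e.g. the shortest contact between arginine terminal nitrogens
#' and glutamate carboxylate oxygens for a salt-bridge metric.
#'
#' @param frame One frame from [read_structure()].
#' @param set_a,set_b Selections: `list(resno =, elety =, chain = NULL)`,
#'   each resolving to one or more atoms.
#' @return Minimum distance in Angstrom.
#' @export
min_pair_distance <- function(frame, set_a, set_b) {
  pa <- do.call(resolve_atoms, c(list(frame), set_a))
  pb <- do.call(resolve_atoms, c(list(frame), set_b))
  d2 <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
              Vectorize(function(i, j) sum((pa[i, ] - pb[j, ])^2)))
  sqrt(min(d2))
}

## Signed dihedral (degrees, (-180, 180]) from four xyz points.
dihedral_xyz <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("collinear atoms: dihedral plane undefined")
  }
  y <- sqrt(sum(b2^2)) * sum(b1 * n2)
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Signed dihedral angle of four atoms
#'
#' Standard atan2 formulation; result in degrees in `(-180, 180]`. A cis
#' arrangement gives 0, trans gives 180.
#'
#' @param frame One frame from [read_structure()].
#' @param sel1,sel2,sel3,sel4 Selections, each resolving to one atom.
#' @return Angle in degrees.
#' @export
dihedral <- function(frame, sel1, sel2, sel3, sel4) {
  pts <- lapply(list(sel1, sel2, sel3, sel4), function(s) {
    p <- do.call(resolve_atoms, c(list(frame), s))
    if (nrow(p) != 1L) stop("dihedral selections must resolve to one atom")
    p[1, ]
  })
  dihedral_xyz(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Backbone psi dihedral of a residue
#'
#' `psi(i) = N(i)-CA(i)-C(i)-N(i+1)`.
#'
#' @param frame One frame from [read_structure()].
#' @param resno Residue number of residue `i`.
#' @param chain Optional chain restriction.
#' @return Angle in degrees.
#' @export
psi_angle <- function(frame, resno, chain = NULL) {
  dihedral(frame,
           list(resno = resno, elety = "N", chain = chain),
           list(resno = resno, elety = "CA", chain = chain),
           list(resno = resno, elety = "C", chain = chain),
           list(resno = resno + 1L, elety = "N", chain = chain))
}

## chi1 fourth-atom name by residue type (N-CA-CB-X).
chi1_gamma_atom <- function(resid) {
  switch(resid,
         SER = "OG", THR = "OG1", VAL = "CG1", ILE = "CG1", CYS = "SG",
         ALA = stop("ALA has no chi1"), GLY = stop("GLY has no chi1"),
         "CG")
}

#' Side-chain chi1 dihedral of a residue
#'
#' `chi1 = N-CA-CB-G` where the gamma atom G depends on residue type
#' (CG for Phe/His/Trp/Leu and most others; OG for Ser, OG1 for Thr,
#' CG1 for Val/Ile, SG for Cys).
#'
#' @param frame One frame from [read_structure()].
#' @param resno Residue number.
#' @param chain Optional chain restriction.
#' @return Angle in degrees.
#' @export
chi1_angle <- function(frame, resno, chain = NULL) {
  sel <- frame$resno == resno
  if (!is.null(chain)) sel <- sel & frame$chain %in% chain
  resid <- unique(frame$resid[sel])
  if (length(resid) != 1L) stop("residue ", resno, " not uniquely resolved")
  g <- chi1_gamma_atom(resid)
  dihedral(frame,
           list(resno = resno, elety = "N", chain = chain),
           list(resno = resno, elety = "CA", chain = chain),
           list(resno = resno, elety = "CB", chain = chain),
           list(resno = resno, elety = g, chain = chain))
}

#' Built-in SHP2 order-parameter set
#'
#' The geometric metrics used to track SHP2 conformational transitions
#' (4DGP/6CRF residue numbering): the R111-E249/E250 salt bridge
#' (shortest terminal-N to carboxylate-O distance), the H114-T218
#' C-alpha distance, the T218 psi dihedral, the W423 CZ3 - P429 CG
#' distance, the F469 chi1 dihedral, the P424 CG - V428 carbonyl-O
#' distance, and the D425-C459 C-alpha distance that tracks WPD-loop
#' closure.
#'
#' @param salt_bridge_cutoff Distance (Angstrom) below which the
#'   R111-E249/E250 salt bridge is called formed (assumed default 4.0;
#'   not an experimentally reported value).
#' @param wpd_closed_cutoff C-alpha distance below which the WPD loop is
#'   called closed (assumed default 10.0).
#' @return List of metric specs for [metric_timeseries()].
#' @export
shp2_metric_specs <- function(salt_bridge_cutoff = 4.0,
                              wpd_closed_cutoff = 10.0) {
  list(
    r111_e249_250_saltbridge = list(
      kind = "min_pair_distance",
      set_a = list(resno = 111, elety = c("NH1", "NH2")),
      set_b = list(resno = c(249, 250), elety = c("OE1", "OE2")),
      states = c(formed = -Inf, broken = salt_bridge_cutoff)
    ),
    h114_t218_ca = list(
      kind = "atom_distance",
      a = list(resno = 114, elety = "CA"),
      b = list(resno = 218, elety = "CA")
    ),
    t218_psi = list(kind = "psi", resno = 218),
    w423_p429 = list(
      kind = "atom_distance",
      a = list(resno = 423, elety = "CZ3"),
      b = list(resno = 429, elety = "CG")
    ),
    f469_chi1 = list(kind = "chi1", resno = 469),
    p424_v428_carbonyl = list(
      kind = "atom_distance",
      a = list(resno = 424, elety = "CG"),
      b = list(resno = 428, elety = "O")
    ),
    wpd_d425_c459_ca = list(
      kind = "atom_distance",
      a = list(resno = 425, elety = "CA"),
      b = list(resno = 459, elety = "CA"),
      states = c(closed = -Inf, open = wpd_closed_cutoff)
    )
  )
}

## Evaluate one metric spec on one frame.
eval_metric <- function(frame, spec) {
  switch(spec$kind,
         atom_distance = atom_distance(frame, spec$a, spec$b),
         min_pair_distance = min_pair_distance(frame, spec$set_a, spec$set_b),
         psi = psi_angle(frame, spec$resno, spec$chain),
         chi1 = chi1_angle(frame, spec$resno, spec$chain),
         stop("unknown metric kind: ", spec$kind))
}

#' Evaluate metric specs across frames
#'
#' Long-format table of every metric in every frame. Specs must resolve
#' in the first frame (hard error otherwise); a spec failing in a later
#' frame yields an `NA` row and the run continues. Specs with a `states`
#' element (named cutoffs: value falls in the interval starting at the
#' named lower bound) get a `state` column.
#'
#' @param frames A [read_structure()] result (or list of frames).
#' @param specs Named list of metric specs (see [shp2_metric_specs()]).
#' @return data.frame: `frame`, `metric`, `value`, `state`.
#' @export
metric_timeseries <- function(frames, specs) {
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("specs must be a named list")
  }
  for (nm in names(specs)) {
    eval_metric(frames[[1]], specs[[nm]])  # must resolve in frame 1
  }
  rows <- list()
  k <- 0L
  for (f in seq_along(frames)) {
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      val <- if (f == 1L) {
        eval_metric(frames[[f]], spec)
      } else {
        tryCatch(eval_metric(frames[[f]], spec),
                 error = function(e) NA_real_)
      }
      state <- NA_character_
      if (!is.null(spec$states) && !is.na(val)) {
        cuts <- sort(spec$states)
        state <- names(cuts)[findInterval(val, cuts)]
      }
      k <- k + 1L
      rows[[k]] <- data.frame(frame = f, metric = nm, value = val,
                              state = state, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a metric time series as TSV
#'
#' @param ts A [metric_timeseries()] table.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_metric_table <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
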