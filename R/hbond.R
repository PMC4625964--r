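# Geometric hydrogen-bond detection and occupancy statistics.
# A donor-H...acceptor triple qualifies when the donor-heavy to acceptor
# distance is strictly less than the cutoff (default 3.5 A) and the angle at
# the hydrogen, subtended by the donor heavy atom and the acceptor, is
# strictly greater than the cutoff (default 120 degrees). Donor/acceptor
# roles come from topology flags; donor hydrogens are the bonded hydrogens
# recorded in the topology bond list.

#' @keywords internal
#' @noRd
.donor_hydrogens <- function(top, donor) {
  if (is.null(top$bonds)) return(integer())
  b <- top$bonds
  partners <- c(b$j[b$i == donor], b$i[b$j == donor])
  partners[top$atoms$element[partners] == "H" | top$atoms$mass[partners] < 3]
}

#' @keywords internal
#' @noRd
.atom_label <- function(top, i) {
  a <- top$atoms
  sprintf("%s%d-%s", a$residue_name[i], a$residue_index[i], a$name[i])
}

#' Detect hydrogen bonds in a single frame
#'
#' Donor heavy atoms are those flagged `is_donor_heavy` within
#' `donors_from`; each of their bonded hydrogens is tested against every
#' atom flagged `is_acceptor` within `acceptors_from`. A donor heavy atom
#' without a recorded hydrogen is skipped with a warning.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param top a [topology()].
#' @param criteria an [hbond_criteria()].
#' @param donors_from,acceptors_from atom index pools (defaults: ligand
#'   donors against receptor acceptors).
#' @return A data frame with one row per qualifying triple: `donor`,
#'   `hydrogen`, `acceptor` (atom indices), `donor_label`, `hydrogen_label`,
#'   `acceptor_label`, `distance` (heavy-heavy, Angstrom), `angle`
#'   (degrees at the hydrogen).
#' @export
detect_hbonds <- function(coords, top, criteria = hbond_criteria(),
                          donors_from = top$ligand,
                          acceptors_from = top$receptor) {
  donors <- donors_from[top$atoms$is_donor_heavy[donors_from]]
  acceptors <- acceptors_from[top$atoms$is_acceptor[acceptors_from]]
  rows <- list()
  for (d in donors) {
    hs <- .donor_hydrogens(top, d)
    if (!length(hs)) {
      warning("donor heavy atom ", d, " has no bonded hydrogen; skipped")
      next
    }
    for (h in hs) for (a in setdiff(acceptors, c(d, h))) {
      dist_da <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (!(dist_da < criteria$max_heavy_distance)) next
      v1 <- coords[d, ] - coords[h, ]
      v2 <- coords[a, ] - coords[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (!(ang > criteria$min_angle)) next
      rows[[length(rows) + 1]] <- data.frame(
        donor = d, hydrogen = h, acceptor = a,
        donor_label = .atom_label(top, d),
        hydrogen_label = .atom_label(top, h),
        acceptor_label = .atom_label(top, a),
        distance = dist_da, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), donor_label = character(),
                      hydrogen_label = character(),
                      acceptor_label = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy of a unique donor-H...acceptor triple is
#' `100 * (qualifying frames) / (total frames)`; the mean distance and
#' angle are taken over qualifying frames only. Records are sorted by
#' decreasing occupancy.
#'
#' @param traj a [trajectory()].
#' @param top a [topology()].
#' @param criteria an [hbond_criteria()].
#' @param donors_from,acceptors_from atom index pools (see
#'   [detect_hbonds()]).
#' @param min_occupancy drop triples below this occupancy (%, default 0).
#' @return A data frame of class `hbond_table`: `donor_label`,
#'   `hydrogen_label`, `acceptor_label`, `mean_distance`, `mean_angle`,
#'   `occupancy`; empty when nothing qualifies.
#' @export
hbond_occupancy <- function(traj, top, criteria = hbond_criteria(),
                            donors_from = top$ligand,
                            acceptors_from = top$receptor,
                            min_occupancy = 0) {
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames")
  tally <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hits <- detect_hbonds(frame_coords(traj, f), top, criteria,
                          donors_from, acceptors_from)
    if (!nrow(hits)) next
    for (r in seq_len(nrow(hits))) {
      key <- paste(hits$donor[r], hits$hydrogen[r], hits$acceptor[r],
                   sep = "_")
      rec <- tally[[key]] %||% list(n = 0, dist = 0, ang = 0, row = hits[r, ])
      rec$n <- rec$n + 1
      rec$dist <- rec$dist + hits$distance[r]
      rec$ang <- rec$ang + hits$angle[r]
      tally[[key]] <- rec
    }
  }
  keys <- ls(tally)
  if (!length(keys))
    return(structure(data.frame(donor_label = character(),
                                hydrogen_label = character(),
                                acceptor_label = character(),
                                mean_distance = numeric(),
                                mean_angle = numeric(),
                                occupancy = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("hbond_table", "data.frame")))
  out <- do.call(rbind, lapply(keys, function(k) {
    rec <- tally[[k]]
    data.frame(donor_label = rec$row$donor_label,
               hydrogen_label = rec$row$hydrogen_label,
               acceptor_label = rec$row$acceptor_label,
               mean_distance = rec$dist / rec$n,
               mean_angle = rec$ang / rec$n,
               occupancy = 100 * rec$n / nf, stringsAsFactors = FALSE)
  }))
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}
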