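# Disulfide detection and geometry from PDB coordinates.

# Cysteine SG atoms from a bio3d pdb object: first model, ATOM records,
# highest-occupancy altloc per (chain, resno).
.cys_sg_atoms <- function(pdb) {
  at <- pdb$atom
  sel <- at$resid %in% c("CYS", "CYX", "CYS2") & at$elety == "SG" &
    at$type == "ATOM"
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0L) return(at)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[which.max(at$o[idx])]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Detect disulfide bonds in a PDB file
#'
#' Finds all unordered pairs of cysteine SG atoms within `cutoff` of each
#' other and pairs them greedily by increasing distance so that each
#' cysteine joins at most one bond. Only the first model is used, and the
#' highest-occupancy alternate location per residue.
#'
#' @param pdb path to a PDB file.
#' @param cutoff SG-SG distance cutoff in Angstrom (default 2.5; a
#'   standard disulfide is about 2.05).
#' @return data.frame (class `disulfide_bonds`) with one row per bond:
#'   `chain1`, `resno1`, `resid1`, `chain2`, `resno2`, `resid2`,
#'   `sg_distance` (Angstrom), `mid_x`, `mid_y`, `mid_z`. Zero rows when
#'   no disulfide is found.
#' @examples
#' detect_disulfides(toy_fixtures()$pdb)
#' @export
detect_disulfides <- function(pdb, cutoff = 2.5) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  obj <- tryCatch(bio3d::read.pdb(pdb, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  sg <- .cys_sg_atoms(obj)
  empty <- data.frame(chain1 = character(0), resno1 = integer(0),
                      resid1 = character(0), chain2 = character(0),
                      resno2 = integer(0), resid2 = character(0),
                      sg_distance = numeric(0), mid_x = numeric(0),
                      mid_y = numeric(0), mid_z = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("disulfide_bonds", "data.frame")
  if (nrow(sg) < 2L) return(empty)
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  n <- nrow(sg)
  cand <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= cutoff) {
        cand <- rbind(cand, c(i, j, d))
      }
    }
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand[, 3L]), , drop = FALSE]
  used <- logical(n)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    mid <- (xyz[i, ] + xyz[j, ]) / 2
    rows[[length(rows) + 1L]] <- data.frame(
      chain1 = sg$chain[i], resno1 = sg$resno[i], resid1 = sg$resid[i],
      chain2 = sg$chain[j], resno2 = sg$resno[j], resid2 = sg$resid[j],
      sg_distance = cand[k, 3L],
      mid_x = mid[1L], mid_y = mid[2L], mid_z = mid[3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("disulfide_bonds", "data.frame")
  out
}

# Parse "chain:resnum:atomname" into its parts.
.parse_selector <- function(site_selector) {
  parts <- strsplit(site_selector, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop("site selector must be 'chain:resnum:atomname', got '",
         site_selector, "'")
  }
  list(chain = parts[1L], resno = as.integer(parts[2L]), elety = parts[3L])
}

#' Distances from disulfide bonds to a reference site atom
#'
#' Distance from the SG-SG midpoint of each bond to a single site atom
#' (for example the catalytic zinc), plus the per-SG distances. HETATM
#' records (metals) are valid site atoms.
#'
#' @param bonds result of [detect_disulfides()].
#' @param pdb path to the PDB file the bonds came from.
#' @param site_selector atom specification `"chain:resnum:atomname"`; must
#'   resolve to exactly one atom.
#' @return data.frame with the bond columns plus `site_distance`,
#'   `sg1_distance`, `sg2_distance` (Angstrom).
#' @export
site_distances <- function(bonds, pdb, site_selector) {
  stopifnot(inherits(bonds, "data.frame"))
  sel <- .parse_selector(site_selector)
  obj <- tryCatch(bio3d::read.pdb(pdb, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  at <- obj$atom
  hit <- at$chain == sel$chain & at$resno == sel$resno & at$elety == sel$elety
  hit[is.na(hit)] <- FALSE
  if (sum(hit) == 0L) stop("site selector '", site_selector,
                           "' matches no atom")
  if (sum(hit) > 1L) stop("site selector '", site_selector, "' matches ",
                          sum(hit), " atoms; expected exactly one")
  site <- as.numeric(at[hit, c("x", "y", "z")])
  sg <- .cys_sg_atoms(obj)
  sg_xyz <- function(chain, resno) {
    r <- sg[sg$chain == chain & sg$resno == resno, , drop = FALSE]
    if (nrow(r) != 1L) stop("cannot locate SG atom of ", chain, ":", resno)
    as.numeric(r[1L, c("x", "y", "z")])
  }
  bonds$site_distance <- NA_real_
  bonds$sg1_distance <- NA_real_
  bonds$sg2_distance <- NA_real_
  for (k in seq_len(nrow(bonds))) {
    p1 <- sg_xyz(bonds$chain1[k], bonds$resno1[k])
    p2 <- sg_xyz(bonds$chain2[k], bonds$resno2[k])
    mid <- (p1 + p2) / 2
    bonds$site_distance[k] <- sqrt(sum((mid - site)^2))
    bonds$sg1_distance[k] <- sqrt(sum((p1 - site)^2))
    bonds$sg2_distance[k] <- sqrt(sum((p2 - site)^2))
  }
  bonds
}

#' Attach secondary-structure labels to detected bonds
#'
#' Secondary structure is consumed, not computed: supply a per-residue
#' H/E/L map (DSSP-style letters reduced to helix/sheet/loop). Residues
#' missing from the map are labelled `"unknown"`.
#'
#' @param bonds result of [detect_disulfides()].
#' @param ss_annotation data.frame with columns `chain`, `resno`, `ss`
#'   (values `"H"`, `"E"`, `"L"`), or a named character vector keyed
#'   `"chain:resno"`.
#' @return `bonds` with columns `ss1`, `ss2` added.
#' @export
attach_ss_labels <- function(bonds, ss_annotation) {
  stopifnot(inherits(bonds, "data.frame"))
  if (is.data.frame(ss_annotation)) {
    stopifnot(all(c("chain", "resno", "ss") %in% names(ss_annotation)))
    map <- stats::setNames(as.character(ss_annotation$ss),
                           paste(ss_annotation$chain, ss_annotation$resno,
                                 sep = ":"))
  } else {
    map <- ss_annotation
  }
  look <- function(chain, resno) {
    v <- map[paste(chain, resno, sep = ":")]
    ifelse(is.na(v), "unknown", v)
  }
  bonds$ss1 <- unname(look(bonds$chain1, bonds$resno1))
  bonds$ss2 <- unname(look(bonds$chain2, bonds$resno2))
  bonds
}
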