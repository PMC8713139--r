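# Hybrid (dual-state) cysteine/cystine residue topologies for alchemical
# disulfide reduction. State A (lambda = 0) is the disulfide-bonded
# half-cystine; state B (lambda = 1) is the free cysteine. The hybrid
# residue ("CYD") carries one dummy atom (HUD) that morphs into the thiol
# hydrogen, plus two interaction-free virtual sites (VC, VS) anchored to
# the CB and S positions.

.DUMMY_TYPE <- "DUM"   # zero-charge, zero-LJ placeholder type
.VSITE_TYPE <- "VST"   # zero-charge, zero-LJ virtual-site type

#' Construct a residue parameter template
#'
#' Atom names, types, charges and masses plus bonded terms (by atom name)
#' for one residue, as consumed by [build_hybrid_residue()]. Templates are
#' user-supplied force-field excerpts; this package ships only minimal toy
#' fixtures.
#'
#' @param name residue name (e.g. `"CYS"`, `"CYS2"`).
#' @param atoms data.frame with columns `name`, `type`, `charge`, `mass`.
#' @param bonds data.frame with columns `ai`, `aj` (atom names).
#' @param angles data.frame with columns `ai`, `aj`, `ak`.
#' @param dihedrals data.frame with columns `ai`, `aj`, `ak`, `al`.
#' @param formal_charge declared total charge of the residue; the atom
#'   charges must sum to it within 1e-6 e.
#' @return An object of class `residue_template`.
#' @export
residue_template <- function(name, atoms, bonds = NULL, angles = NULL,
                             dihedrals = NULL, formal_charge = 0) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "type", "charge", "mass") %in% names(atoms)))
  atoms <- data.frame(name = as.character(atoms$name),
                      type = as.character(atoms$type),
                      charge = as.numeric(atoms$charge),
                      mass = as.numeric(atoms$mass),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in template")
  if (abs(sum(atoms$charge) - formal_charge) > 1e-6) {
    stop(sprintf("atom charges sum to %.6f, declared formal charge is %.6f",
                 sum(atoms$charge), formal_charge))
  }
  norm_terms <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0L) {
      return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                           cols), stringsAsFactors = FALSE))
    }
    stopifnot(all(cols %in% names(df)))
    out <- df[, cols, drop = FALSE]
    out[] <- lapply(out, as.character)
    unknown <- setdiff(unlist(out), atoms$name)
    if (length(unknown)) {
      stop("bonded term references unknown atom(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    rownames(out) <- NULL
    out
  }
  structure(
    list(name = as.character(name)[1L], atoms = atoms,
         bonds = norm_terms(bonds, c("ai", "aj")),
         angles = norm_terms(angles, c("ai", "aj", "ak")),
         dihedrals = norm_terms(dihedrals, c("ai", "aj", "ak", "al")),
         formal_charge = as.numeric(formal_charge)),
    class = "residue_template"
  )
}

#' @export
print.residue_template <- function(x, ...) {
  cat(sprintf("<residue_template> %s: %d atoms, %d bonds, %d angles, %d dihedrals, q = %g e\n",
              x$name, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals), x$formal_charge))
  invisible(x)
}

#' Read a residue template from an itp-like text file
#'
#' Format: `;` starts a comment; `[ meta ]`, `[ atoms ]`, `[ bonds ]`,
#' `[ angles ]`, `[ dihedrals ]` sections. The meta section holds
#' `name <residue>` and `formal_charge <q>`; atom lines are
#' `name type charge mass`; bonded-term lines list atom names.
#'
#' @param path file path.
#' @return A [residue_template()].
#' @export
read_residue_template <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  section <- ""
  meta <- list(name = NULL, formal_charge = 0)
  at <- list(); bd <- list(); an <- list(); dh <- list()
  for (i in seq_along(lines)) {
    ln <- sub(";.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("[][ ]", "", ln))
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (section == "meta") {
      if (tok[1L] == "name") meta$name <- tok[2L]
      if (tok[1L] == "formal_charge") meta$formal_charge <- as.numeric(tok[2L])
    } else if (section == "atoms") {
      if (length(tok) != 4L) stop("bad atom line ", i, " in '", path, "'")
      at[[length(at) + 1L]] <- tok
    } else if (section == "bonds") {
      bd[[length(bd) + 1L]] <- tok[1:2]
    } else if (section == "angles") {
      an[[length(an) + 1L]] <- tok[1:3]
    } else if (section == "dihedrals") {
      dh[[length(dh) + 1L]] <- tok[1:4]
    }
  }
  if (is.null(meta$name)) stop("template '", path, "' lacks a meta name")
  to_df <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), cols)
  }
  atoms <- to_df(at, c("name", "type", "charge", "mass"))
  if (is.null(atoms)) stop("template '", path, "' has no atoms")
  residue_template(meta$name, atoms,
                   bonds = to_df(bd, c("ai", "aj")),
                   angles = to_df(an, c("ai", "aj", "ak")),
                   dihedrals = to_df(dh, c("ai", "aj", "ak", "al")),
                   formal_charge = meta$formal_charge)
}

#' Build a dual-state hybrid residue from cystine and cysteine templates
#'
#' Constructs the hybrid residue "CYD": state A is the disulfide-bonded
#' half-cystine template, state B the free cysteine template. The thiol
#' hydrogen present only in the cysteine template is realized by a dummy
#' atom `HUD` (zero charge, zero-LJ type, no bonded terms in state A;
#' full hydrogen in state B). Two virtual sites `VC` and `VS` are added,
#' position-constrained to the CB-bonded carbon and the sulfur; they carry
#' no charge or dispersion interaction in either state.
#'
#' @param cystine_template [residue_template()] of the disulfide-bonded
#'   (oxidized) cysteine; its atoms must be a subset of the cysteine
#'   template's, lacking exactly the thiol hydrogen.
#' @param cysteine_template [residue_template()] of the free (reduced)
#'   cysteine.
#' @return An object of class `hybrid_residue`.
#' @examples
#' tpl <- toy_fixtures()
#' hyb <- build_hybrid_residue(read_residue_template(tpl$cystine),
#'                             read_residue_template(tpl$cysteine))
#' nrow(hyb$atoms)  # cysteine atom count + 2 virtual sites
#' @export
build_hybrid_residue <- function(cystine_template, cysteine_template) {
  stopifnot(inherits(cystine_template, "residue_template"),
            inherits(cysteine_template, "residue_template"))
  ox <- cystine_template; red <- cysteine_template
  only_ox <- setdiff(ox$atoms$name, red$atoms$name)
  if (length(only_ox)) {
    stop("atom-name mismatch: cystine atoms absent from cysteine template: ",
         paste(only_ox, collapse = ", "))
  }
  thiol <- setdiff(red$atoms$name, ox$atoms$name)
  if (length(thiol) != 1L) {
    stop("expected exactly one cysteine-only atom (the thiol hydrogen); ",
         "found: ", if (length(thiol)) paste(thiol, collapse = ", ") else "none")
  }
  # the thiol hydrogen's bonded partner is the sulfur
  tb <- red$bonds
  hit <- tb$ai == thiol | tb$aj == thiol
  if (sum(hit) != 1L) {
    stop("thiol hydrogen '", thiol, "' must have exactly one bond in the ",
         "cysteine template")
  }
  sulfur <- setdiff(unlist(tb[hit, c("ai", "aj")]), thiol)
  # CB: the sulfur's other bonded partner in the cystine template
  ob <- ox$bonds
  s_part <- setdiff(unlist(ob[ob$ai == sulfur | ob$aj == sulfur, c("ai", "aj")]),
                    sulfur)
  if (length(s_part) != 1L) {
    stop("sulfur '", sulfur, "' must have exactly one intra-residue bond ",
         "partner in the cystine template")
  }
  cb <- s_part
  red_at <- red$atoms
  # atom order follows the cysteine template (HUD sits in the thiol slot),
  # so both end-state projections reproduce their template's ordering; the
  # templates must therefore agree on the ordering of the shared atoms
  if (!identical(ox$atoms$name, red_at$name[red_at$name != thiol])) {
    stop("atom-name mismatch: cystine atom order (",
         paste(ox$atoms$name, collapse = ", "),
         ") must equal the cysteine order minus the thiol hydrogen (",
         paste(red_at$name[red_at$name != thiol], collapse = ", "), ")")
  }
  th_row <- red_at[red_at$name == thiol, ]
  is_th <- red_at$name == thiol
  a_idx <- match(red_at$name, ox$atoms$name)   # NA at the thiol slot
  n_red <- nrow(red_at)
  atoms <- data.frame(
    name = c(ifelse(is_th, "HUD", red_at$name), "VC", "VS"),
    kind = c(ifelse(is_th, "dummy", "real"), "vsite", "vsite"),
    anchor = c(rep(NA_character_, n_red), cb, sulfur),
    typeA = c(ifelse(is_th, .DUMMY_TYPE, ox$atoms$type[a_idx]),
              .VSITE_TYPE, .VSITE_TYPE),
    chargeA = c(ifelse(is_th, 0, ox$atoms$charge[a_idx]), 0, 0),
    massA = c(ifelse(is_th, th_row$mass, ox$atoms$mass[a_idx]), 0, 0),
    typeB = c(red_at$type, .VSITE_TYPE, .VSITE_TYPE),
    chargeB = c(red_at$charge, 0, 0),
    massB = c(red_at$mass, 0, 0),
    stringsAsFactors = FALSE
  )
  rename_thiol <- function(df) {
    df[] <- lapply(df, function(col) ifelse(col == thiol, "HUD", col))
    df
  }
  structure(
    list(name = "CYD", atoms = atoms,
         bonded_A = list(bonds = ox$bonds, angles = ox$angles,
                         dihedrals = ox$dihedrals),
         bonded_B = list(bonds = rename_thiol(red$bonds),
                         angles = rename_thiol(red$angles),
                         dihedrals = rename_thiol(red$dihedrals)),
         a_name = ox$name, b_name = red$name, thiol_name = thiol,
         sulfur = sulfur, cb = cb,
         formal_charge_A = ox$formal_charge,
         formal_charge_B = red$formal_charge),
    class = "hybrid_residue"
  )
}

#' @export
print.hybrid_residue <- function(x, ...) {
  cat(sprintf("<hybrid_residue> %s: %d atoms (A = %s, B = %s; S = %s, CB anchor = %s)\n",
              x$name, nrow(x$atoms), x$a_name, x$b_name, x$sulfur, x$cb))
  invisible(x)
}

#' Project a hybrid residue onto one end state
#'
#' State `"A"` (lambda = 0) drops the dummy atom and virtual sites and
#' returns the half-cystine description; state `"B"` (lambda = 1) drops
#' the virtual sites, renames `HUD` back to the thiol hydrogen, and
#' returns the free-cysteine description. A correctly built hybrid
#' projects exactly onto its input templates.
#'
#' @param hybrid a [build_hybrid_residue()] result.
#' @param state `"A"` or `"B"`.
#' @return A [residue_template()].
#' @export
project_state <- function(hybrid, state = c("A", "B")) {
  stopifnot(inherits(hybrid, "hybrid_residue"))
  state <- match.arg(state)
  at <- hybrid$atoms
  if (state == "A") {
    keep <- at[at$kind == "real", ]
    atoms <- data.frame(name = keep$name, type = keep$typeA,
                        charge = keep$chargeA, mass = keep$massA,
                        stringsAsFactors = FALSE)
    bt <- hybrid$bonded_A
    residue_template(hybrid$a_name, atoms, bt$bonds, bt$angles, bt$dihedrals,
                     formal_charge = hybrid$formal_charge_A)
  } else {
    keep <- at[at$kind %in% c("real", "dummy"), ]
    nm <- ifelse(keep$name == "HUD", hybrid$thiol_name, keep$name)
    atoms <- data.frame(name = nm, type = keep$typeB,
                        charge = keep$chargeB, mass = keep$massB,
                        stringsAsFactors = FALSE)
    restore <- function(df) {
      df[] <- lapply(df, function(col) ifelse(col == "HUD", hybrid$thiol_name, col))
      df
    }
    bt <- hybrid$bonded_B
    residue_template(hybrid$b_name, atoms, restore(bt$bonds),
                     restore(bt$angles), restore(bt$dihedrals),
                     formal_charge = hybrid$formal_charge_B)
  }
}

#' Cross-residue bonded terms of a disulfide-bonded hybrid pair
#'
#' The oxidized (A) state of a bonded CYD pair carries bonded interactions
#' spanning the two residues: the S1-S2 bond, the CB1-S1-S2 and
#' CB2-S2-S1 angles, and every dihedral with S1-S2 as its central bond
#' (enumerated from the A-state intra-residue connectivity). All of these
#' are absent in state B, where the residues are two independent free
#' cysteines.
#'
#' Atom references are qualified `"1:<name>"` / `"2:<name>"` for the first
#' and second residue of the pair.
#'
#' @param res1,res2 [build_hybrid_residue()] results (must be CYD hybrids).
#' @return An object of class `cross_bond_terms` with data.frames `bond`,
#'   `angles`, `dihedrals` and field `state = "A"`.
#' @export
pair_cross_terms <- function(res1, res2) {
  for (r in list(res1, res2)) {
    if (!inherits(r, "hybrid_residue") || !identical(r$name, "CYD")) {
      stop("pair_cross_terms() requires two CYD hybrid residues")
    }
  }
  q1 <- function(x) paste0("1:", x)
  q2 <- function(x) paste0("2:", x)
  s1 <- res1$sulfur; s2 <- res2$sulfur
  neighbours <- function(res) {
    b <- res$bonded_A$bonds
    setdiff(unlist(b[b$ai == res$sulfur | b$aj == res$sulfur, c("ai", "aj")]),
            res$sulfur)
  }
  n1 <- neighbours(res1)   # within res1, excludes S2 (inter-residue)
  n2 <- neighbours(res2)
  dihedrals <- expand.grid(x = n1, y = n2, stringsAsFactors = FALSE)
  dihedrals <- data.frame(ai = q1(dihedrals$x), aj = q1(s1), ak = q2(s2),
                          al = q2(dihedrals$y), stringsAsFactors = FALSE)
  structure(
    list(bond = data.frame(ai = q1(s1), aj = q2(s2), stringsAsFactors = FALSE),
         angles = data.frame(ai = c(q1(res1$cb), q2(res2$cb)),
                             aj = c(q1(s1), q2(s2)),
                             ak = c(q2(s2), q1(s1)), stringsAsFactors = FALSE),
         dihedrals = dihedrals,
         state = "A"),
    class = "cross_bond_terms"
  )
}

#' @export
print.cross_bond_terms <- function(x, ...) {
  cat(sprintf("<cross_bond_terms> state %s: 1 bond, %d angles, %d dihedrals\n",
              x$state, nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}

# ---- perturbed-topology writer/reader (dialect v1) -------------------------
#
# A documented subset of the GROMACS itp grammar with A/B state columns:
#   [ residue <i> ] with meta lines, then [ atoms ] rows
#     name kind anchor typeA chargeA massA typeB chargeB massB
#   and [ bonds ]/[ angles ]/[ dihedrals ] rows with a trailing state flag
#   A, B or AB; terms present in one state only have no parameters in the
#   other (flag rule). [ constraints ] records the virtual-site anchors.
#   [ cross <i> <j> ] holds the A-state-only inter-residue terms.

.term_union <- function(tA, tB, cols) {
  keyify <- function(df) if (nrow(df)) do.call(paste, c(df[cols], sep = "|")) else character(0)
  kA <- keyify(tA); kB <- keyify(tB)
  all_k <- unique(c(kA, kB))
  if (!length(all_k)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df$state <- character(0)
    return(df)
  }
  parts <- do.call(rbind, strsplit(all_k, "|", fixed = TRUE))
  df <- stats::setNames(as.data.frame(parts, stringsAsFactors = FALSE), cols)
  df$state <- ifelse(all_k %in% kA & all_k %in% kB, "AB",
                     ifelse(all_k %in% kA, "A", "B"))
  df
}

#' Write hybrid residues and cross terms as a perturbed topology file
#'
#' Emits the dual-column A/B topology dialect (see the package vignette):
#' per-atom type/charge/mass columns for both states, per-term state flags
#' (`A`, `B`, or `AB`), virtual-site anchors as constraint records, and
#' the A-state-only cross-residue terms of each disulfide pair.
#' [read_perturbed_topology()] reconstructs an equal structure.
#'
#' @param residues list of [build_hybrid_residue()] results.
#' @param cross list of [pair_cross_terms()] results; element `k` couples
#'   residues `2k - 1` and `2k`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_perturbed_topology <- function(residues, cross, path) {
  if (inherits(residues, "hybrid_residue")) residues <- list(residues)
  if (inherits(cross, "cross_bond_terms")) cross <- list(cross)
  stopifnot(all(vapply(residues, inherits, logical(1), "hybrid_residue")))
  out <- c("; redoxbond perturbed topology, dialect v1",
           "; per-atom columns: name kind anchor typeA chargeA massA typeB chargeB massB",
           "; per-term trailing flag: A (lambda=0 only), B (lambda=1 only), AB (both)")
  fmt_num <- function(x) sprintf("%.17g", x)
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    out <- c(out, sprintf("[ residue %d ]", i),
             paste("name", r$name),
             paste("state_a", r$a_name), paste("state_b", r$b_name),
             paste("thiol", r$thiol_name),
             paste("sulfur", r$sulfur), paste("cb", r$cb),
             paste("formal_charge_a", fmt_num(r$formal_charge_A)),
             paste("formal_charge_b", fmt_num(r$formal_charge_B)),
             "[ atoms ]")
    at <- r$atoms
    out <- c(out, sprintf("%s %s %s %s %s %s %s %s %s",
                          at$name, at$kind,
                          ifelse(is.na(at$anchor), "-", at$anchor),
                          at$typeA, fmt_num(at$chargeA), fmt_num(at$massA),
                          at$typeB, fmt_num(at$chargeB), fmt_num(at$massB)))
    for (sec in c("bonds", "angles", "dihedrals")) {
      cols <- switch(sec, bonds = c("ai", "aj"),
                     angles = c("ai", "aj", "ak"),
                     dihedrals = c("ai", "aj", "ak", "al"))
      u <- .term_union(r$bonded_A[[sec]], r$bonded_B[[sec]], cols)
      out <- c(out, sprintf("[ %s ]", sec))
      if (nrow(u)) {
        out <- c(out, do.call(paste, c(u[cols], list(u$state))))
      }
    }
    vs <- at[at$kind == "vsite", ]
    out <- c(out, "[ constraints ]",
             sprintf("%s = %s", vs$name, vs$anchor))
  }
  for (k in seq_along(cross)) {
    x <- cross[[k]]
    out <- c(out, sprintf("[ cross %d %d ]", 2L * k - 1L, 2L * k),
             "[ bond ]",
             paste(x$bond$ai, x$bond$aj, x$state),
             "[ angles ]",
             paste(x$angles$ai, x$angles$aj, x$angles$ak, x$state),
             "[ dihedrals ]")
    if (nrow(x$dihedrals)) {
      out <- c(out, paste(x$dihedrals$ai, x$dihedrals$aj, x$dihedrals$ak,
                          x$dihedrals$al, x$state))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a perturbed topology file back into hybrid structures
#'
#' Inverse of [write_perturbed_topology()].
#'
#' @param path file path.
#' @return List with `residues` (list of `hybrid_residue`) and `cross`
#'   (list of `cross_bond_terms`).
#' @export
read_perturbed_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  residues <- list(); cross <- list()
  cur <- NULL; cur_cross <- NULL; section <- ""
  term_cols <- list(bonds = c("ai", "aj"), angles = c("ai", "aj", "ak"),
                    dihedrals = c("ai", "aj", "ak", "al"),
                    bond = c("ai", "aj"))
  empty_terms <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  flush_residue <- function() {
    if (is.null(cur)) return()
    split_terms <- function(sec) {
      cols <- term_cols[[sec]]
      rows <- cur$terms[[sec]]
      if (is.null(rows)) rows <- list()
      df <- if (length(rows)) {
        m <- do.call(rbind, rows)
        stats::setNames(as.data.frame(m[, seq_along(cols), drop = FALSE],
                                      stringsAsFactors = FALSE), cols)
      } else empty_terms(cols)
      st <- if (length(rows)) vapply(rows, function(r) r[length(cols) + 1L],
                                     character(1)) else character(0)
      list(A = df[st %in% c("A", "AB"), , drop = FALSE],
           B = df[st %in% c("B", "AB"), , drop = FALSE])
    }
    b <- split_terms("bonds"); a <- split_terms("angles"); d <- split_terms("dihedrals")
    reset_rows <- function(df) { rownames(df) <- NULL; df }
    res <- structure(
      list(name = cur$meta$name,
           atoms = cur$atoms,
           bonded_A = list(bonds = reset_rows(b$A), angles = reset_rows(a$A),
                           dihedrals = reset_rows(d$A)),
           bonded_B = list(bonds = reset_rows(b$B), angles = reset_rows(a$B),
                           dihedrals = reset_rows(d$B)),
           a_name = cur$meta$state_a, b_name = cur$meta$state_b,
           thiol_name = cur$meta$thiol, sulfur = cur$meta$sulfur,
           cb = cur$meta$cb,
           formal_charge_A = as.numeric(cur$meta$formal_charge_a),
           formal_charge_B = as.numeric(cur$meta$formal_charge_b)),
      class = "hybrid_residue")
    residues[[length(residues) + 1L]] <<- res
    cur <<- NULL
  }
  flush_cross <- function() {
    if (is.null(cur_cross)) return()
    mk <- function(sec, cols) {
      rows <- cur_cross$terms[[sec]]
      if (is.null(rows) || !length(rows)) return(empty_terms(cols))
      m <- do.call(rbind, rows)
      stats::setNames(as.data.frame(m[, seq_along(cols), drop = FALSE],
                                    stringsAsFactors = FALSE), cols)
    }
    cross[[length(cross) + 1L]] <<- structure(
      list(bond = mk("bond", c("ai", "aj")),
           angles = mk("angles", c("ai", "aj", "ak")),
           dihedrals = mk("dihedrals", c("ai", "aj", "ak", "al")),
           state = "A"),
      class = "cross_bond_terms")
    cur_cross <<- NULL
  }
  for (raw in lines) {
    ln <- trimws(sub(";.*$", "", raw))
    if (ln == "") next
    if (grepl("^\\[ residue", ln)) {
      flush_cross(); flush_residue()
      cur <- list(meta = list(), atoms = NULL, terms = list())
      section <- "residue_meta"
      next
    }
    if (grepl("^\\[ cross", ln)) {
      flush_cross(); flush_residue()
      cur_cross <- list(terms = list())
      section <- "cross_meta"
      next
    }
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (!is.null(cur_cross)) {
      cur_cross$terms[[section]] <- c(cur_cross$terms[[section]], list(tok))
    } else if (!is.null(cur)) {
      if (section == "residue_meta") {
        cur$meta[[tok[1L]]] <- tok[2L]
      } else if (section == "atoms") {
        row <- data.frame(name = tok[1L], kind = tok[2L],
                          anchor = ifelse(tok[3L] == "-", NA_character_, tok[3L]),
                          typeA = tok[4L], chargeA = as.numeric(tok[5L]),
                          massA = as.numeric(tok[6L]), typeB = tok[7L],
                          chargeB = as.numeric(tok[8L]),
                          massB = as.numeric(tok[9L]),
                          stringsAsFactors = FALSE)
        cur$atoms <- rbind(cur$atoms, row)
      } else if (section %in% c("bonds", "angles", "dihedrals")) {
        cur$terms[[section]] <- c(cur$terms[[section]], list(tok))
      }
      # constraints are redundant with atom anchors; skipped on read
    }
  }
  flush_cross(); flush_residue()
  residues <- lapply(residues, function(r) { rownames(r$atoms) <- NULL; r })
  list(residues = residues, cross = cross)
}

#' Validate a hybrid residue against its end-state templates
#'
#' Itemized pass/fail per construction invariant: end-state projections
#' equal the templates field-for-field, the dummy atom is neutral and
#' interaction-free in state A, virtual sites are neutral in both states,
#' and the state-B charges sum to the cysteine formal charge.
#'
#' @param hybrid a [build_hybrid_residue()] result (possibly modified).
#' @param cystine,cysteine the reference [residue_template()]s.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_state_equivalence <- function(hybrid, cystine, cysteine) {
  stopifnot(inherits(hybrid, "hybrid_residue"))
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = isTRUE(pass), detail = detail,
      stringsAsFactors = FALSE)
  }
  proj <- function(state) tryCatch(project_state(hybrid, state),
                                   error = function(e) NULL)
  same_df <- function(x, y) isTRUE(all.equal(x, y, check.attributes = FALSE))
  pA <- proj("A"); pB <- proj("B")
  add("A_atoms_equal_cystine",
      !is.null(pA) && same_df(pA$atoms, cystine$atoms))
  add("A_bonded_equal_cystine",
      !is.null(pA) && same_df(pA$bonds, cystine$bonds) &&
        same_df(pA$angles, cystine$angles) &&
        same_df(pA$dihedrals, cystine$dihedrals))
  add("B_atoms_equal_cysteine",
      !is.null(pB) && same_df(pB$atoms, cysteine$atoms))
  add("B_bonded_equal_cysteine",
      !is.null(pB) && same_df(pB$bonds, cysteine$bonds) &&
        same_df(pB$angles, cysteine$angles) &&
        same_df(pB$dihedrals, cysteine$dihedrals))
  at <- hybrid$atoms
  hud <- at[at$kind == "dummy", ]
  add("dummy_neutral_in_A", nrow(hud) == 1L && all(hud$chargeA == 0),
      "HUD must carry zero charge at lambda = 0")
  add("dummy_zero_LJ_in_A", nrow(hud) == 1L && all(hud$typeA == .DUMMY_TYPE),
      "HUD must use the zero-LJ dummy type at lambda = 0")
  vs <- at[at$kind == "vsite", ]
  add("vsites_neutral_both_states",
      nrow(vs) == 2L && all(vs$chargeA == 0) && all(vs$chargeB == 0) &&
        all(vs$typeA == .VSITE_TYPE) && all(vs$typeB == .VSITE_TYPE))
  add("B_charge_sum_matches_cysteine",
      abs(sum(at$chargeB[at$kind %in% c("real", "dummy")]) -
            cysteine$formal_charge) <= 1e-6)
  do.call(rbind, checks)
}
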