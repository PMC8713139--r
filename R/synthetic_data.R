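# Synthetic inputs with the statistical structure the analysis assumes:
# Crooks-consistent Gaussian work samples at known dG, dH/dlambda series
# with prescribed integrals, and toy structure/topology fixtures.

#' Crooks-consistent Gaussian work model
#'
#' Under the Crooks fluctuation theorem, a Gaussian forward work
#' distribution with variance sigma^2 forces the negated backward
#' distribution to be Gaussian with the same variance, the two means
#' straddling the free energy by the dissipation
#' `beta sigma^2 / 2`:
#' forward mean `dG + beta sigma^2 / 2`, negated-backward mean
#' `dG - beta sigma^2 / 2`. This is the unique Gaussian pair satisfying
#' `P_F(W) / P_B(-W) = exp(beta (W - dG))`, so dissipation is
#' parameterized by `sigma` alone.
#'
#' @param dG_true ground-truth free energy, kJ/mol.
#' @param sigma work standard deviation, kJ/mol (> 0).
#' @param temperature kelvin (default 300).
#' @param n_per_direction replicas per direction (default 500, the usual
#'   fast-switching protocol scale).
#' @param seed integer seed.
#' @return An object of class `cft_model`.
#' @export
cft_model <- function(dG_true, sigma, temperature = 300,
                      n_per_direction = 500, seed = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  if (n_per_direction < 1) stop("'n_per_direction' must be >= 1")
  structure(
    list(dG_true = as.numeric(dG_true), sigma = as.numeric(sigma),
         temperature = as.numeric(temperature),
         beta = beta_from_temperature(temperature),
         n_per_direction = as.integer(n_per_direction),
         seed = as.integer(seed)),
    class = "cft_model"
  )
}

#' @export
print.cft_model <- function(x, ...) {
  cat(sprintf("<cft_model> dG = %g kJ/mol, sigma = %g, T = %g K, n = %d/direction, seed = %d\n",
              x$dG_true, x$sigma, x$temperature, x$n_per_direction, x$seed))
  invisible(x)
}

#' Sample forward/backward work sets from a Crooks-consistent model
#'
#' Forward works are drawn from `N(dG + beta sigma^2/2, sigma^2)`.
#' Backward works are stored in the backward frame: the negated draws of
#' `N(dG - beta sigma^2/2, sigma^2)`, i.e. the work done along the
#' backward path itself. Deterministic given the model seed.
#'
#' @param model a [cft_model()].
#' @param label label for the generated work sets.
#' @return List with elements `forward` and `backward` ([work_set()]s)
#'   and `model`.
#' @examples
#' p <- sample_cft_works(cft_model(30, 4, n_per_direction = 100, seed = 7))
#' mean(p$forward$works)        # about 30 + beta*16/2
#' @export
sample_cft_works <- function(model, label = "bond") {
  stopifnot(inherits(model, "cft_model"))
  diss <- model$beta * model$sigma^2 / 2
  draws <- with_seed(model$seed, {
    list(f = rnorm(model$n_per_direction, model$dG_true + diss, model$sigma),
         b = rnorm(model$n_per_direction, model$dG_true - diss, model$sigma))
  })
  list(forward = work_set(label, "forward", draws$f, model$temperature),
       backward = work_set(label, "backward", -draws$b, model$temperature),
       model = model)
}

#' Synthetic dH/dlambda series with a prescribed integral
#'
#' A smooth sinusoidal base curve plus seeded Gaussian noise, shifted by a
#' constant so that the trapezoidal integral along the series' own path
#' equals `target_work` exactly (the shift is exact because the lambda
#' path has unit measure).
#'
#' @param target_work desired work value, kJ/mol.
#' @param n_points number of lambda samples (>= 2; default 101).
#' @param noise_sd pointwise noise standard deviation, kJ/mol.
#' @param seed integer seed (`NULL` = do not touch the RNG).
#' @param direction `"forward"` (lambda 0 -> 1) or `"backward"` (1 -> 0).
#' @param replica_id identifier for the series.
#' @return A [dhdl_series()] with `integrate_work(series) == target_work`.
#' @examples
#' s <- synth_dhdl(25, n_points = 51, noise_sd = 2, seed = 3)
#' integrate_work(s)
#' @export
synth_dhdl <- function(target_work, n_points = 101, noise_sd = 0,
                       seed = NULL, direction = "forward",
                       replica_id = "synthetic") {
  direction <- match.arg(direction, c("forward", "backward"))
  if (n_points < 2L) stop("'n_points' must be >= 2")
  lam <- seq(0, 1, length.out = n_points)
  if (direction == "backward") lam <- rev(lam)
  amp <- 0.3 * abs(target_work) + 1
  y <- amp * sin(pi * lam)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(n_points, 0, noise_sd))
  }
  s0 <- dhdl_series(replica_id, direction, lam, y)
  w0 <- integrate_work(s0)
  # integral of a constant c over the path is +c (forward) or -c (backward)
  path_sign <- if (direction == "forward") 1 else -1
  shift <- (target_work - w0) / path_sign
  dhdl_series(replica_id, direction, lam, y + shift)
}

#' Generate a labelled panel of synthetic disulfide-bond work sets
#'
#' One Crooks-consistent model per bond, with the ground-truth free
#' energy, raw and corrected potentials, and role recorded in a truth
#' table. Defaults mimic a realistic study design: 17 bonds with 500 work
#' values per direction at 300 K.
#'
#' @param n_bonds number of bonds (>= 1; default 17).
#' @param dG_range interval (kJ/mol) from which true free energies are
#'   drawn uniformly (default 17-50, the span of typical disulfide
#'   reduction work values).
#' @param sigma work standard deviation, kJ/mol (default 4).
#' @param n_per_direction replicas per direction (default 500).
#' @param temperature kelvin (default 300).
#' @param seed integer seed; per-bond seeds are derived as `seed + i`.
#' @param dG_values optional explicit true free energies (length
#'   `n_bonds`), overriding `dG_range`.
#' @param model a [calibration_model()] used for the truth table.
#' @param policy a [classification_policy()] used for the truth table.
#' @return List with `bonds` (list of `bond_id`, `domain`, `forward`,
#'   `backward`) and `truth` (data.frame `bond_id`, `dG_true`, `E_cal`,
#'   `E_corr`, `role`).
#' @examples
#' pan <- make_bond_panel(n_bonds = 3, n_per_direction = 50, seed = 1)
#' pan$truth
#' @export
make_bond_panel <- function(n_bonds = 17, dG_range = c(17, 50), sigma = 4,
                            n_per_direction = 500, temperature = 300,
                            seed = 1, dG_values = NULL,
                            model = calibration_model(),
                            policy = classification_policy()) {
  if (n_bonds < 1) stop("'n_bonds' must be >= 1")
  if (is.null(dG_values)) {
    if (length(dG_range) != 2L || dG_range[2L] < dG_range[1L]) {
      stop("'dG_range' must be an interval c(lo, hi)")
    }
    dG_values <- with_seed(seed, runif(n_bonds, dG_range[1L], dG_range[2L]))
  } else if (length(dG_values) != n_bonds) {
    stop("'dG_values' must have length n_bonds")
  }
  bonds <- vector("list", n_bonds)
  for (i in seq_len(n_bonds)) {
    id <- sprintf("bond%02d", i)
    m <- cft_model(dG_values[i], sigma, temperature, n_per_direction,
                   seed = seed + i)
    s <- sample_cft_works(m, label = id)
    bonds[[i]] <- list(bond_id = id, domain = "synthetic",
                       forward = s$forward, backward = s$backward,
                       model = m)
  }
  E_cal <- nernst_potential(dG_values)
  E_corr <- calibrate(E_cal, model)
  truth <- data.frame(bond_id = vapply(bonds, `[[`, character(1), "bond_id"),
                      dG_true = dG_values, E_cal = E_cal, E_corr = E_corr,
                      role = classify_role(E_corr, policy),
                      stringsAsFactors = FALSE)
  list(bonds = bonds, truth = truth, seed = seed, sigma = sigma,
       n_per_direction = n_per_direction, temperature = temperature)
}

#' Write a bond panel's work values as a single work-table CSV
#'
#' @param panel result of [make_bond_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bond_panel <- function(panel, path) {
  sets <- unlist(lapply(panel$bonds, function(b) list(b$forward, b$backward)),
                 recursive = FALSE)
  write_workset(sets, path)
}

#' Paths to the packaged toy fixtures
#'
#' Deterministic plain-text fixtures: a two-cysteine toy peptide with an
#' SG-SG separation of 2.05 Angstrom plus a zinc site, minimal cysteine
#' and half-cystine residue templates (synthetic stand-ins mimicking the
#' relevant force-field entries, not redistributed parameters), and the
#' published LOXL2 disulfide table.
#'
#' @return Named list of file paths: `pdb`, `cysteine`, `cystine`, `table`.
#' @export
toy_fixtures <- function() {
  p <- function(f) system.file("extdata", f, package = "redoxbond",
                               mustWork = TRUE)
  list(pdb = p("toy_disulfide.pdb"),
       cysteine = p("template_cysteine.rtp"),
       cystine = p("template_cystine.rtp"),
       table = p("loxl2_disulfide_table.csv"))
}

#' Write a toy disulfide PDB file
#'
#' Generates a minimal peptide of cysteine residues whose SG atoms are
#' placed at the supplied coordinates, with CB atoms offset 1.8 Angstrom
#' in +y and backbone N/CA atoms nearby, plus an optional zinc HETATM.
#' Used to build structure-analysis fixtures programmatically.
#'
#' @param path output path.
#' @param sg_xyz numeric matrix (n x 3) of SG coordinates, one row per
#'   cysteine.
#' @param zn_xyz optional length-3 vector: coordinates of a zinc atom
#'   (chain Z, residue 999, atom ZN).
#' @param chain chain identifier for the peptide.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(path, sg_xyz, zn_xyz = NULL, chain = "A") {
  sg_xyz <- matrix(as.numeric(sg_xyz), ncol = 3L)
  rec <- function(serial, name, resid, chain, resno, xyz, elem,
                  type = "ATOM") {
    nm <- if (nchar(name) < 4L) paste0(" ", name) else name
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, nm, resid, chain, resno,
            xyz[1L], xyz[2L], xyz[3L], 1.00, 0.00, elem)
  }
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(sg_xyz))) {
    sg <- sg_xyz[i, ]
    cb <- sg + c(0, 1.8, 0)
    ca <- sg + c(0, 3.3, 0)
    nn <- sg + c(1.0, 4.2, 0)
    for (a in list(list("N", nn, "N"), list("CA", ca, "C"),
                   list("CB", cb, "C"), list("SG", sg, "S"))) {
      serial <- serial + 1L
      lines <- c(lines, rec(serial, a[[1L]], "CYS", chain, i, a[[2L]],
                            a[[3L]]))
    }
  }
  if (!is.null(zn_xyz)) {
    serial <- serial + 1L
    lines <- c(lines, rec(serial, "ZN", "ZN", "Z", 999L,
                          as.numeric(zn_xyz), "ZN", type = "HETATM"))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
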