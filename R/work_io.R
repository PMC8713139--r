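# Work I/O: dH/dlambda series, trapezoidal work integration, work tables.

#' Construct a dH/dlambda series for one switching replica
#'
#' An ordered set of (lambda, dH/dlambda) samples along one alchemical
#' switching trajectory. Forward replicas run lambda 0 -> 1 (oxidized to
#' reduced), backward replicas 1 -> 0; lambda must be strictly monotone in
#' the direction of travel.
#'
#' @param replica_id identifier for the replica (character scalar).
#' @param direction `"forward"` or `"backward"`.
#' @param lambda numeric vector of coupling-parameter values in \[0, 1\],
#'   strictly increasing (forward) or strictly decreasing (backward).
#' @param dhdl numeric vector of dH/dlambda values, kJ/mol per unit lambda.
#' @return An object of class `dhdl_series`.
#' @seealso [read_dhdl()], [integrate_work()]
#' @examples
#' s <- dhdl_series("r1", "forward", c(0, 0.5, 1), c(5, 5, 5))
#' integrate_work(s)
#' @export
dhdl_series <- function(replica_id, direction, lambda, dhdl) {
  direction <- match.arg(direction, c("forward", "backward"))
  lambda <- as.numeric(lambda)
  dhdl <- as.numeric(dhdl)
  if (length(lambda) != length(dhdl)) {
    stop("'lambda' and 'dhdl' must have equal length")
  }
  if (length(lambda) < 2L) {
    stop("a dhdl series needs at least 2 points")
  }
  if (anyNA(lambda) || anyNA(dhdl) || !all(is.finite(lambda) & is.finite(dhdl))) {
    stop("non-finite values in dhdl series")
  }
  if (any(lambda < 0) || any(lambda > 1)) {
    stop("lambda values must lie in [0, 1]")
  }
  dl <- diff(lambda)
  if (any(dl == 0)) {
    stop("duplicate lambda values in dhdl series")
  }
  if (direction == "forward" && any(dl <= 0)) {
    stop("forward series requires strictly increasing lambda")
  }
  if (direction == "backward" && any(dl >= 0)) {
    stop("backward series requires strictly decreasing lambda")
  }
  structure(
    list(replica_id = as.character(replica_id)[1L], direction = direction,
         lambda = lambda, dhdl = dhdl),
    class = "dhdl_series"
  )
}

#' @export
print.dhdl_series <- function(x, ...) {
  cat(sprintf("<dhdl_series> replica %s, %s, %d points, lambda %g -> %g\n",
              x$replica_id, x$direction, length(x$lambda),
              x$lambda[1L], x$lambda[length(x$lambda)]))
  invisible(x)
}

#' Read a dH/dlambda series from an xvg-style text file
#'
#' Lines starting with `#` or `@` are treated as comments/metadata (the
#' convention of GROMACS xvg output). Data lines hold at least two
#' whitespace-separated numbers: lambda (or time, see `time_range`) and
#' dH/dlambda in kJ/mol.
#'
#' @param path path to the file.
#' @param direction `"forward"` or `"backward"`.
#' @param replica_id identifier to attach; defaults to the file name.
#' @param time_range optional `c(t_start, t_end)`: the first column is a
#'   time that is mapped linearly onto lambda in \[0, 1\] (forward) or
#'   \[1, 0\] (backward). When `NULL` (default) the first column is taken
#'   to be lambda already.
#' @return A [dhdl_series()].
#' @examples
#' f <- tempfile(fileext = ".xvg")
#' writeLines(c("@ title dhdl", "0.0 5.0", "1.0 5.0"), f)
#' read_dhdl(f, "forward")
#' @export
read_dhdl <- function(path, direction, replica_id = basename(path),
                      time_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lam <- numeric(0)
  dhdl <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "@")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (length(tok) < 2L) {
      stop(sprintf("parse error at line %d of '%s': expected >=2 columns", i, path))
    }
    vals <- suppressWarnings(as.numeric(tok[1:2]))
    if (anyNA(vals)) {
      stop(sprintf("parse error at line %d of '%s': non-numeric token", i, path))
    }
    lam <- c(lam, vals[1L])
    dhdl <- c(dhdl, vals[2L])
  }
  if (length(lam) < 2L) {
    stop("input error: fewer than 2 data points in '", path, "'")
  }
  if (!is.null(time_range)) {
    if (length(time_range) != 2L || time_range[2L] <= time_range[1L]) {
      stop("'time_range' must be c(t_start, t_end) with t_end > t_start")
    }
    s <- (lam - time_range[1L]) / (time_range[2L] - time_range[1L])
    lam <- if (direction == "backward") 1 - s else s
  }
  dhdl_series(replica_id, direction, lam, dhdl)
}

#' Integrate a dH/dlambda series to a work value
#'
#' Trapezoidal integration of dH/dlambda over lambda in the order the
#' series was sampled. A forward series yields the work along the 0 -> 1
#' path; a backward series is integrated along its own 1 -> 0 path, so its
#' work carries the sign of that path (negation into the forward frame
#' happens inside the estimators, not here).
#'
#' @param series a [dhdl_series()].
#' @return Work in kJ/mol (scalar).
#' @examples
#' integrate_work(dhdl_series("r", "forward", c(0, .25, .5, .75, 1),
#'                            2 * c(0, .25, .5, .75, 1)))  # exactly 1
#' @export
integrate_work <- function(series) {
  stopifnot(inherits(series, "dhdl_series"))
  if (any(diff(series$lambda) == 0)) {
    stop("duplicate lambda values in dhdl series")
  }
  pracma::trapz(series$lambda, series$dhdl)
}

#' Construct a work set
#'
#' A labelled collection of scalar work values for one transition direction
#' at one temperature. Backward works are stored as the work done along the
#' backward (reduced -> oxidized) path itself.
#'
#' @param label bond or transition identifier.
#' @param direction `"forward"` or `"backward"`.
#' @param works numeric vector of work values, kJ/mol; must be finite and
#'   non-empty.
#' @param temperature temperature in kelvin (default 300).
#' @return An object of class `work_set`.
#' @examples
#' work_set("b1", "forward", c(29.1, 31.2, 30.4))
#' @export
work_set <- function(label, direction, works, temperature = 300) {
  direction <- match.arg(direction, c("forward", "backward"))
  works <- as.numeric(works)
  if (length(works) == 0L) stop("'works' must be non-empty")
  if (anyNA(works) || !all(is.finite(works))) {
    stop("non-finite work values are not allowed")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("'temperature' must be a single positive number (kelvin)")
  }
  structure(
    list(label = as.character(label)[1L], direction = direction,
         works = works, temperature = as.numeric(temperature)),
    class = "work_set"
  )
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> %s (%s): n = %d, mean = %.3f kJ/mol, T = %g K\n",
              x$label, x$direction, length(x$works), mean(x$works),
              x$temperature))
  invisible(x)
}

# Format doubles so that read-back reproduces them bit-for-bit.
.fmt_full <- function(x) sprintf("%.17g", x)

#' Write a work set to CSV
#'
#' Columns `label,direction,work_kJ_mol,temperature_K`; work values are
#' written with 17 significant digits so a read/write round trip is exact.
#'
#' @param ws a [work_set()] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_workset()], [read_work_table()]
#' @export
write_workset <- function(ws, path) {
  if (inherits(ws, "work_set")) ws <- list(ws)
  stopifnot(all(vapply(ws, inherits, logical(1), "work_set")))
  rows <- lapply(ws, function(w) {
    data.frame(label = w$label, direction = w$direction,
               work_kJ_mol = .fmt_full(w$works),
               temperature_K = .fmt_full(w$temperature),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a work table CSV into a list of work sets
#'
#' The file must have header columns `label,direction,work_kJ_mol` and an
#' optional `temperature_K`. Rows are grouped by (label, direction); one
#' [work_set()] is returned per group.
#'
#' @param path CSV path.
#' @return Named list of [work_set()] objects; names are
#'   `"<label>.<direction>"`.
#' @export
read_work_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("label", "direction", "work_kJ_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("work table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("input error: work table has no data rows")
  bad <- setdiff(unique(tab$direction), c("forward", "backward"))
  if (length(bad)) {
    stop("unknown direction token(s): ", paste(bad, collapse = ", "))
  }
  w <- suppressWarnings(as.numeric(tab$work_kJ_mol))
  if (anyNA(w)) stop("non-numeric work value in work table")
  temp <- if ("temperature_K" %in% names(tab)) {
    tt <- suppressWarnings(as.numeric(tab$temperature_K))
    if (anyNA(tt)) stop("non-numeric temperature in work table")
    tt
  } else rep(300, nrow(tab))
  key <- paste(tab$label, tab$direction, sep = ".")
  out <- lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))),
                function(idx) {
                  tk <- unique(temp[idx])
                  if (length(tk) != 1L) {
                    stop("inconsistent temperature within group '", key[idx[1]], "'")
                  }
                  work_set(tab$label[idx[1L]], tab$direction[idx[1L]],
                           w[idx], tk)
                })
  out
}

#' Read a single work set from CSV
#'
#' Convenience wrapper around [read_work_table()] for files holding exactly
#' one (label, direction) group, optionally after filtering.
#'
#' @param path CSV path.
#' @param label,direction optional filters selecting one group.
#' @return A [work_set()].
#' @export
read_workset <- function(path, label = NULL, direction = NULL) {
  sets <- read_work_table(path)
  if (!is.null(label)) {
    sets <- Filter(function(w) w$label == label, sets)
  }
  if (!is.null(direction)) {
    sets <- Filter(function(w) w$direction == direction, sets)
  }
  if (length(sets) == 0L) stop("no matching work set in '", path, "'")
  if (length(sets) > 1L) {
    stop("file holds ", length(sets),
         " work sets; use read_work_table() or filter by label/direction")
  }
  sets[[1L]]
}
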