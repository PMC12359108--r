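#' @useDynLib dpimd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm setNames aggregate
#' @importFrom utils write.csv read.csv head
NULL

# Unit system used throughout: Angstrom, femtosecond, amu, eV.
# One conversion constant relates them: 1 eV = EV_AA amu A^2 / fs^2, so that
# acceleration [A/fs^2] = force [eV/A] * EV_AA / mass [amu] and
# kinetic energy [eV] = 0.5 * sum(m v^2) / EV_AA.
EV_AA <- 9.648533215665e-3

#' Physical constants
#'
#' Boltzmann constant in eV/K, used for all temperature bookkeeping.
#' @export
KB_EV <- 8.617333e-5

# Average atomic weights (amu). Average (not monoisotopic) weights reproduce
# the conventional fragment mass labels, e.g. CO = 28.01 vs HCNH = 28.03.
ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Atomic species table
#'
#' Average atomic weights for the elements handled by the package.
#'
#' @return Data frame with columns `symbol` and `mass` (amu).
#' @export
atomic_species <- function() {
  data.frame(symbol = names(ATOMIC_WEIGHTS), mass = unname(ATOMIC_WEIGHTS),
             stringsAsFactors = FALSE)
}

#' Look up atomic masses
#'
#' @param symbols Character vector of element symbols.
#' @return Numeric vector of average atomic weights (amu).
#' @export
atomic_masses <- function(symbols) {
  m <- ATOMIC_WEIGHTS[symbols]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Molecular state container
#'
#' Bundles element symbols, Cartesian positions and velocities in the
#' package unit system (Angstrom, Angstrom/fs, amu).
#'
#' @param symbols Character vector of element symbols (length N >= 1).
#' @param positions N x 3 numeric matrix of coordinates (Angstrom).
#' @param velocities N x 3 numeric matrix (Angstrom/fs); defaults to zero.
#' @return Object of class `molecular_system` with derived `masses` (amu).
#' @export
molecular_system <- function(symbols, positions, velocities = NULL) {
  positions <- as.matrix(positions)
  n <- length(symbols)
  if (n < 1L) stop("need at least one atom")
  if (nrow(positions) != n || ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix matching symbols")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (nrow(velocities) != n || ncol(velocities) != 3L)
    stop("velocities must be an N x 3 matrix matching symbols")
  structure(list(symbols = as.character(symbols),
                 positions = unname(positions),
                 velocities = unname(velocities),
                 masses = atomic_masses(symbols)),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", length(x$symbols), " atoms: ",
      formula_string(molecular_formula(x)), "\n", sep = "")
  invisible(x)
}

#' Molecular formula of an atom subset
#'
#' @param system A `molecular_system`.
#' @param atom_index_set Integer indices of the atoms to count; defaults to
#'   all atoms.
#' @return Object of class `fragment_formula`: a named integer vector of
#'   element counts with the canonical Hill-order string as attribute.
#' @export
molecular_formula <- function(system, atom_index_set = seq_along(system$symbols)) {
  if (length(atom_index_set) == 0L) stop("empty atom index set")
  if (any(atom_index_set < 1L | atom_index_set > length(system$symbols)))
    stop("atom index out of range")
  syms <- system$symbols[atom_index_set]
  bad <- setdiff(unique(syms), names(ATOMIC_WEIGHTS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(syms, levels = names(ATOMIC_WEIGHTS)))
  counts <- counts[counts > 0L]
  out <- setNames(as.integer(counts), names(counts))
  class(out) <- "fragment_formula"
  attr(out, "string") <- hill_string(out)
  out
}

# Hill order: C first, then H, then remaining elements alphabetically.
hill_string <- function(counts) {
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

#' Canonical formula string
#'
#' @param formula A `fragment_formula` or a formula string such as "C2H3N".
#' @return Hill-order formula string.
#' @export
formula_string <- function(formula) {
  if (inherits(formula, "fragment_formula")) return(attr(formula, "string"))
  hill_string(parse_formula(formula))
}

#' @export
print.fragment_formula <- function(x, ...) {
  cat("<fragment_formula> ", attr(x, "string"), " (",
      sprintf("%.2f", fragment_mass(x)), " amu)\n", sep = "")
  invisible(x)
}

# "C3NH3O" -> c(C = 3, N = 1, H = 3, O = 1)
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  m <- gregexpr("[A-Z][a-z]?\\d*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", s)
  counts <- integer(0)
  for (t in toks) {
    el <- gsub("\\d", "", t)
    k <- gsub("\\D", "", t)
    k <- if (nzchar(k)) as.integer(k) else 1L
    if (!el %in% names(ATOMIC_WEIGHTS)) stop("unknown element symbol(s): ", el)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  counts
}

#' Fragment mass
#'
#' Mass of a fragment from average atomic weights. `mass_label()` gives the
#' conventional two-decimal label; `mass_bin()` the nearest-integer m/z bin.
#'
#' @param formula A `fragment_formula` or formula string.
#' @return Mass in amu (numeric).
#' @export
fragment_mass <- function(formula) {
  counts <- if (inherits(formula, "fragment_formula")) unclass(formula)
            else parse_formula(formula)
  if (length(counts) == 0L || sum(counts) == 0L) stop("empty formula")
  sum(atomic_masses(names(counts)) * as.numeric(counts))
}

#' @rdname fragment_mass
#' @export
mass_label <- function(formula) round(fragment_mass(formula), 2)

#' @rdname fragment_mass
#' @export
mass_bin <- function(formula) as.integer(round(fragment_mass(formula)))

#' Kinetic energy and center-of-mass momentum
#'
#' @param system A `molecular_system`.
#' @return `kinetic_energy()`: total nuclear kinetic energy in eV.
#'   `center_of_mass_momentum()`: length-3 momentum vector (amu Angstrom/fs).
#' @export
kinetic_energy <- function(system) {
  sum(0.5 * system$masses * rowSums(system$velocities^2)) / EV_AA
}

#' @rdname kinetic_energy
#' @export
center_of_mass_momentum <- function(system) {
  colSums(system$masses * system$velocities)
}

#' Read and write (extended) XYZ files
#'
#' Multi-frame XYZ with `key=value` metadata on the comment line
#' (`time_fs`, `E_tot_eV`, `charge`) and optional velocity columns.
#'
#' @param path File path.
#' @return `read_xyz()`: list of `molecular_system` frames, each with
#'   attributes `time_fs`, `E_tot_eV`, `charge` when present in the file.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed XYZ header at line ", i)
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop("atom-count mismatch: expected ", n, " atoms at line ", i)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    ncol_body <- unique(lengths(fields))
    if (length(ncol_body) != 1L || !ncol_body %in% c(4L, 7L))
      stop("malformed atom line near line ", i + 2L)
    syms <- vapply(fields, `[[`, character(1), 1L)
    num <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(ncol_body - 1L)))
    vel <- if (ncol_body == 7L) num[, 4:6, drop = FALSE] else NULL
    sys <- molecular_system(syms, num[, 1:3, drop = FALSE], vel)
    for (kv in parse_kv(comment)) attr(sys, kv$key) <- kv$value
    frames[[length(frames) + 1L]] <- sys
    i <- i + 2L + n
  }
  frames
}

parse_kv <- function(comment) {
  toks <- regmatches(comment, gregexpr("[A-Za-z_][A-Za-z0-9_]*=[^ ]+", comment))[[1]]
  lapply(toks, function(t) {
    kv <- strsplit(t, "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(kv[2]))
    list(key = kv[1], value = if (is.na(val)) kv[2] else val)
  })
}

#' @rdname read_xyz
#' @param frames A `molecular_system` or list of them; frames may carry
#'   `time_fs`, `E_tot_eV`, `charge` attributes which are written as
#'   `key=value` pairs on the comment line.
#' @param write_velocities Include velocity columns (default TRUE).
#' @export
write_xyz <- function(frames, path, write_velocities = TRUE) {
  if (inherits(frames, "molecular_system")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (sys in frames) {
    n <- length(sys$symbols)
    meta <- character(0)
    for (key in c("time_fs", "E_tot_eV", "charge")) {
      v <- attr(sys, key)
      if (!is.null(v)) meta <- c(meta, paste0(key, "=", format(v, digits = 12)))
    }
    writeLines(as.character(n), con)
    writeLines(paste(meta, collapse = " "), con)
    mat <- if (write_velocities) cbind(sys$positions, sys$velocities)
           else sys$positions
    writeLines(paste0(formatC(sys$symbols, width = -2),
                      apply(mat, 1L, function(r)
                        paste(sprintf("% .10f", r), collapse = " "))), con)
  }
  invisible(path)
}
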