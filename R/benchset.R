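#' Energy unit conversion
#'
#' Conversion factor between hartree (used for per-species energy components)
#' and kcal/mol (used for process reference energies and all error metrics).
#'
#' @format A length-one numeric: kcal/mol per hartree.
#' @export
kcal_per_hartree <- 627.509474

#' Parse a Hill-order molecular formula
#'
#' Converts a formula string such as `"C2H6O"` into a named integer vector of
#' element counts. Element symbols are one capital letter optionally followed
#' by one lowercase letter; a missing count means 1.
#'
#' @param formula A character vector of formula strings.
#' @return A list (one entry per input string) of named integer vectors.
#' @examples
#' parse_formula("C2H6O")
#' parse_formula(c("H2O", "FeCl3"))
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  lapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      stop("empty formula string", call. = FALSE)
    }
    m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop(sprintf("malformed formula '%s'", f), call. = FALSE)
    }
    sym <- sub("[0-9]+$", "", toks)
    cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
    cnt[is.na(cnt)] <- 1L
    counts <- tapply(cnt, sym, sum)
    out <- as.integer(counts)
    names(out) <- names(counts)
    out
  })
}

#' Format an element-count vector as a Hill-order formula
#'
#' Inverse of [parse_formula()]: carbon first, then hydrogen, then remaining
#' elements alphabetically (plain alphabetical when no carbon is present).
#'
#' @param counts A named integer vector of element counts.
#' @return A formula string.
#' @export
format_formula <- function(counts) {
  stopifnot(length(counts) >= 1, !is.null(names(counts)), all(counts >= 1))
  sym <- names(counts)
  if ("C" %in% sym) {
    ord <- c(
      which(sym == "C"), which(sym == "H"),
      setdiff(order(sym), c(which(sym == "C"), which(sym == "H")))
    )
  } else {
    ord <- order(sym)
  }
  paste0(sym[ord], ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Construct a benchmark set (benchset)
#'
#' A benchset bundles a species table (per-species seven-component energy
#' vectors, in hartree) with an ordered table of chemical processes. Each
#' process is a stoichiometric combination of species with a reference energy
#' in kcal/mol and a subset label.
#'
#' @param name Benchset name.
#' @param species A data frame with columns `id`, `formula`, and `c1`...`c7`
#'   (component energies in hartree).
#' @param processes A data frame with columns `id`, `subset`, `ref_kcal`, and
#'   a list column `stoich` of named numeric vectors (names are species ids,
#'   values are stoichiometric coefficients).
#' @return An object of class `benchset`.
#' @seealso [read_benchset()], [generate_benchset()]
#' @export
benchset <- function(name, species, processes) {
  b <- structure(
    list(name = name, species = species, processes = processes),
    class = "benchset"
  )
  validate_benchset(b)
  b
}

#' Validate a benchset
#'
#' Checks the structural invariants: unique non-empty species ids, seven finite
#' components per species, parseable formulas, at least one process, non-zero
#' stoichiometric coefficients, every referenced species present, and finite
#' reference energies.
#'
#' @param b A `benchset`.
#' @return `b`, invisibly; errors describe the offending row.
#' @export
validate_benchset <- function(b) {
  stopifnot(inherits(b, "benchset"))
  sp <- b$species
  pr <- b$processes
  need_sp <- c("id", "formula", paste0("c", 1:7))
  if (!all(need_sp %in% names(sp))) {
    stop(
      "species table missing column(s): ",
      paste(setdiff(need_sp, names(sp)), collapse = ", "),
      call. = FALSE
    )
  }
  need_pr <- c("id", "subset", "ref_kcal", "stoich")
  if (!all(need_pr %in% names(pr))) {
    stop(
      "process table missing column(s): ",
      paste(setdiff(need_pr, names(pr)), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(sp) == 0) stop("benchset has no species", call. = FALSE)
  if (nrow(pr) == 0) stop("benchset has no processes", call. = FALSE)
  if (anyDuplicated(sp$id)) {
    stop(
      "duplicate species id(s): ",
      paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  comp <- as.matrix(sp[, paste0("c", 1:7)])
  if (!is.numeric(comp) || any(!is.finite(comp))) {
    bad <- sp$id[!apply(is.finite(comp), 1, all)]
    stop(
      "non-finite/non-numeric component(s) for species: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  parse_formula(sp$formula) # errors on malformed formulas
  for (j in seq_len(nrow(pr))) {
    st <- pr$stoich[[j]]
    if (length(st) < 1 || is.null(names(st))) {
      stop(sprintf("process '%s': empty stoichiometry", pr$id[j]), call. = FALSE)
    }
    if (any(st == 0) || any(!is.finite(st))) {
      stop(sprintf("process '%s': zero or non-finite coefficient", pr$id[j]),
        call. = FALSE
      )
    }
    unknown <- setdiff(names(st), sp$id)
    if (length(unknown)) {
      stop(
        sprintf(
          "process '%s' references unknown species: %s",
          pr$id[j], paste(unknown, collapse = ", ")
        ),
        call. = FALSE
      )
    }
  }
  if (any(!is.finite(pr$ref_kcal))) {
    stop(
      "non-finite reference energy for process(es): ",
      paste(pr$id[!is.finite(pr$ref_kcal)], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(b)
}

#' @export
print.benchset <- function(x, ...) {
  cat(sprintf(
    "benchset '%s': %d processes over %d species\n",
    x$name, nrow(x$processes), nrow(x$species)
  ))
  tab <- table(x$processes$subset)
  cat(
    "subsets:",
    paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
    "\n"
  )
  cat(sprintf("elements: %s\n", paste(unique_elements(x), collapse = " ")))
  invisible(x)
}

#' Number of processes in a benchset
#' @param b A `benchset`.
#' @return Integer count.
#' @export
n_processes <- function(b) {
  stopifnot(inherits(b, "benchset"))
  nrow(b$processes)
}

#' Unique chemical elements of a benchset
#'
#' The union of the element multisets of all species that appear in at least
#' one process of the benchset (species never referenced do not count). This
#' is the N_el quantity used by the element-diversity bias in curation.
#'
#' @param b A `benchset`.
#' @return A sorted character vector of element symbols.
#' @export
unique_elements <- function(b) {
  stopifnot(inherits(b, "benchset"))
  used <- unique(unlist(lapply(b$processes$stoich, names)))
  rows <- b$species$formula[b$species$id %in% used]
  sort(unique(unlist(lapply(parse_formula(rows), names))))
}

#' Restrict a benchset to a subset of its processes
#'
#' @param b A `benchset`.
#' @param idx Integer indices into the process table (order preserved as
#'   given), or a character vector of process ids.
#' @param name Name for the restricted benchset.
#' @param drop_species Drop species not referenced by the kept processes
#'   (default `FALSE`, so a family of subsets can share one species table).
#' @return A `benchset`.
#' @export
subset_benchset <- function(b, idx, name = b$name, drop_species = FALSE) {
  stopifnot(inherits(b, "benchset"))
  if (is.character(idx)) idx <- match(idx, b$processes$id)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > nrow(b$processes))) {
    stop("process indices out of range", call. = FALSE)
  }
  pr <- b$processes[idx, , drop = FALSE]
  rownames(pr) <- NULL
  sp <- b$species
  if (drop_species) {
    used <- unique(unlist(lapply(pr$stoich, names)))
    sp <- sp[sp$id %in% used, , drop = FALSE]
    rownames(sp) <- NULL
  }
  benchset(name, sp, pr)
}

#' Split a benchset by its subset labels
#'
#' @param b A `benchset`.
#' @return A named list of benchsets, one per subset label (label order =
#'   first appearance), all sharing the parent species table.
#' @export
split_by_subset <- function(b) {
  stopifnot(inherits(b, "benchset"))
  labs <- unique(b$processes$subset)
  out <- lapply(labs, function(l) {
    subset_benchset(b, which(b$processes$subset == l), name = l)
  })
  names(out) <- labs
  out
}

#' Combine benchsets sharing compatible species tables
#'
#' @param ... Benchsets. Species tables are merged by id; conflicting
#'   component values for the same id are an error.
#' @param name Name of the combined benchset.
#' @return A `benchset` with processes concatenated in argument order.
#' @export
combine_benchsets <- function(..., name = "combined") {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "benchset")))
  sp <- do.call(rbind, lapply(sets, `[[`, "species"))
  dup <- duplicated(sp$id)
  if (any(dup)) {
    first <- sp[!dup, , drop = FALSE]
    for (i in which(dup)) {
      ref <- first[first$id == sp$id[i], , drop = FALSE]
      if (!isTRUE(all.equal(as.numeric(ref[1, paste0("c", 1:7)]),
        as.numeric(sp[i, paste0("c", 1:7)]),
        tolerance = 0
      ))) {
        stop(sprintf("conflicting species definitions for '%s'", sp$id[i]),
          call. = FALSE
        )
      }
    }
    sp <- first
  }
  rownames(sp) <- NULL
  pr <- do.call(rbind, lapply(sets, `[[`, "processes"))
  pr$id <- make.unique(pr$id)
  rownames(pr) <- NULL
  benchset(name, sp, pr)
}

#' Read a benchset from species/processes CSV files
#'
#' File layout: `species.csv` has columns `id,formula,c1,...,c7` (components
#' in hartree); `processes.csv` has columns
#' `id,benchset,subset,stoichiometry,ref_kcal`, where `stoichiometry` is a
#' semicolon-joined list of `species_id:coefficient` terms
#' (e.g. `"H2:-1;O2:-0.5;H2O:1"`). Row order is preserved.
#'
#' @param species_path Path to the species CSV.
#' @param processes_path Path to the processes CSV.
#' @param name Optional benchset name; defaults to the `benchset` column of
#'   the processes file (which must then be constant).
#' @return A validated `benchset`.
#' @export
read_benchset <- function(species_path, processes_path, name = NULL) {
  sp <- utils::read.csv(species_path, stringsAsFactors = FALSE)
  need_sp <- c("id", "formula", paste0("c", 1:7))
  if (!all(need_sp %in% names(sp))) {
    stop(
      sprintf(
        "%s: missing column(s) %s", species_path,
        paste(setdiff(need_sp, names(sp)), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  for (cc in paste0("c", 1:7)) {
    if (!is.numeric(sp[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(sp[[cc]]))))[1]
      stop(
        sprintf(
          "%s: non-numeric value in column %s (row %d)",
          species_path, cc, bad
        ),
        call. = FALSE
      )
    }
  }
  pr_raw <- utils::read.csv(processes_path, stringsAsFactors = FALSE)
  need_pr <- c("id", "benchset", "subset", "stoichiometry", "ref_kcal")
  if (!all(need_pr %in% names(pr_raw))) {
    stop(
      sprintf(
        "%s: missing column(s) %s", processes_path,
        paste(setdiff(need_pr, names(pr_raw)), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  if (!is.numeric(pr_raw$ref_kcal)) {
    stop(sprintf("%s: non-numeric ref_kcal", processes_path), call. = FALSE)
  }
  stoich <- lapply(seq_len(nrow(pr_raw)), function(j) {
    terms <- strsplit(pr_raw$stoichiometry[j], ";", fixed = TRUE)[[1]]
    parts <- strsplit(terms, ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop(
        sprintf(
          "%s row %d: malformed stoichiometry '%s'",
          processes_path, j, pr_raw$stoichiometry[j]
        ),
        call. = FALSE
      )
    }
    v <- as.numeric(vapply(parts, `[`, "", 2))
    if (any(is.na(v))) {
      stop(sprintf("%s row %d: non-numeric coefficient", processes_path, j),
        call. = FALSE
      )
    }
    names(v) <- vapply(parts, `[`, "", 1)
    v
  })
  if (is.null(name)) {
    name <- unique(pr_raw$benchset)
    if (length(name) != 1) {
      stop("processes file contains multiple benchset names; pass `name`",
        call. = FALSE
      )
    }
  }
  pr <- data.frame(
    id = pr_raw$id, subset = pr_raw$subset,
    ref_kcal = pr_raw$ref_kcal, stringsAsFactors = FALSE
  )
  pr$stoich <- stoich
  benchset(name, sp[, need_sp], pr)
}

#' Write a benchset to species/processes CSV files
#'
#' Writes the two-file layout documented in [read_benchset()]. Numeric values
#' are written at 12 significant digits, so a read/write round trip is
#' lossless at that precision.
#'
#' @param b A `benchset`.
#' @param species_path Output path for the species CSV.
#' @param processes_path Output path for the processes CSV.
#' @return Invisibly, the two paths.
#' @export
write_benchset <- function(b, species_path, processes_path) {
  validate_benchset(b)
  sp <- b$species[, c("id", "formula", paste0("c", 1:7))]
  for (cc in paste0("c", 1:7)) sp[[cc]] <- sprintf("%.12g", sp[[cc]])
  utils::write.csv(sp, species_path, row.names = FALSE, quote = FALSE)
  stoich_str <- vapply(b$processes$stoich, function(st) {
    paste(sprintf("%s:%.12g", names(st), st), collapse = ";")
  }, "")
  pr <- data.frame(
    id = b$processes$id, benchset = b$name,
    subset = b$processes$subset, stoichiometry = stoich_str,
    ref_kcal = sprintf("%.12g", b$processes$ref_kcal),
    stringsAsFactors = FALSE
  )
  utils::write.csv(pr, processes_path, row.names = FALSE, quote = FALSE)
  invisible(c(species_path, processes_path))
}
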