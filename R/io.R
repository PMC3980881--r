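#' Read a peptide sequence from FASTA
#'
#' Reads a (single- or multi-record) FASTA file and returns the selected
#' record as a `protein_instance`.
#'
#' @param path FASTA file path.
#' @param record Record index (default 1).
#' @param angle_set Passed to [enumerate_variables()].
#' @return A `protein_instance`.
#' @export
read_fasta_instance <- function(path, record = 1L,
                                angle_set = c("phi", "psi", "chi")) {
  stopifnot(file.exists(path))
  fa <- bio3d::read.fasta(path)
  if (record > nrow(fa$ali)) {
    stop("read_fasta_instance: record ", record, " requested but file has ",
         nrow(fa$ali), call. = FALSE)
  }
  seqv <- fa$ali[record, ]
  seqv <- seqv[!seqv %in% c("-", ".")]
  enumerate_variables(paste(seqv, collapse = ""), angle_set = angle_set)
}

#' Write a conformation as a PDB file
#'
#' Builds the Cartesian chain for the conformation and writes ATOM
#' records (occupancy 1.00, element column populated; side-chain
#' pseudo-atoms are emitted as carbons). The N-terminal anchor atom is a
#' construction aid and is not written.
#'
#' @param instance A `protein_instance`.
#' @param conformation Numeric vector of `m` angles in degrees.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_pdb_conformation <- function(instance, conformation, path) {
  geom <- build_coordinates(instance, conformation)
  keep <- geom$atoms$class != "anchor"
  at <- geom$atoms[keep, , drop = FALSE]
  xyz <- geom$xyz[keep, , drop = FALSE]
  elety <- ifelse(grepl("^X", at$name), paste0("C", substring(at$name, 2)),
                  at$name)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    resno = at$residue,
    resid = bio3d::aa123(instance$residues)[at$residue],
    eleno = seq_len(nrow(at)),
    elety = elety,
    chain = "A",
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at)),
    elesy = substr(ifelse(grepl("^X", at$name), "C", at$name), 1, 1)
  )
  invisible(path)
}

#' Read CA coordinates from a PDB file
#'
#' Convenience reader for dRMSD references: returns the CA coordinate
#' matrix of the first chain of a PDB file.
#'
#' @param path PDB file path.
#' @return An N x 3 coordinate matrix.
#' @export
read_pdb_ca <- function(path) {
  stopifnot(file.exists(path))
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
}

#' Generate deterministic test fixtures
#'
#' Writes self-contained inputs for runs and comparisons; the same seed
#' always yields byte-identical files.
#' \describe{
#'   \item{random_peptide}{a FASTA file with a random sequence of the
#'     given `length` over the 20 standard residues.}
#'   \item{planted}{a YAML spec of a planted landscape (m, traps, seed)
#'     whose certified optimum is reconstructed by
#'     [landscape_from_spec()].}
#'   \item{table7_suite}{paired YAML run configurations for the three
#'     variants at shared seeds, for variant-comparison tables.}
#' }
#'
#' @param kind One of "random_peptide", "planted", "table7_suite".
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param length Peptide length (random_peptide; default 5).
#' @param m,n_traps Landscape shape (planted; defaults 19 and 5).
#' @param seeds Seed count (table7_suite; default 10).
#' @return Character vector of the files written.
#' @export
generate_fixture <- function(kind = c("random_peptide", "planted",
                                      "table7_suite"),
                             dir, seed = 1L, length = 5L, m = 19L,
                             n_traps = 5L, seeds = 10L) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  switch(kind,
    random_peptide = {
      seqc <- paste(sample(names(CHI_COUNTS), length, replace = TRUE),
                    collapse = "")
      path <- file.path(dir, sprintf("peptide_%s.fasta", seqc))
      writeLines(c(sprintf(">random_peptide seed=%d", seed), seqc), path)
      path
    },
    planted = {
      path <- file.path(dir, sprintf("planted_m%d_seed%d.yaml", m, seed))
      yaml::write_yaml(list(kind = "planted", m = as.integer(m),
                            n_traps = as.integer(n_traps),
                            seed = as.integer(seed)), path)
      path
    },
    table7_suite = {
      paths <- character(0)
      for (variant in c("cmqa", "mqa_dep", "csa")) {
        for (s in seq_len(seeds)) {
          cfg <- cmqa_config(variant = variant, seed = seed + s - 1L)
          p <- file.path(dir, sprintf("%s_seed%02d.yaml", variant, s))
          save_config(cfg, p)
          paths <- c(paths, p)
        }
      }
      paths
    }
  )
}

#' Rebuild a planted landscape from its fixture spec
#'
#' @param path YAML file written by `generate_fixture("planted", ...)`.
#' @return A `planted_landscape` (identical to the one the spec encodes).
#' @export
landscape_from_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  stopifnot(identical(spec$kind, "planted"))
  planted_landscape(m = spec$m, n_traps = spec$n_traps, seed = spec$seed)
}

#' Summarize runs into a comparison table
#'
#' Aggregates `cmqa_result` objects into per-group rows with the three
#' reporting metrics: mean best energy, mean wall time (minutes) and,
#' when a reference structure is available, mean dRMSD. Grouping is by
#' variant (and by annealing factor and chaotic map for sweep runs).
#'
#' @param results List of `cmqa_result` objects (>= 1).
#' @param reference Optional reference for dRMSD: a `chain_geometry` or
#'   CA coordinate matrix; requires protein objectives.
#' @return A data frame with one row per group: group keys, `mean_energy`,
#'   `mean_minutes`, `mean_drmsd` (NA without a reference), `n_runs`.
#' @export
summarize_runs <- function(results, reference = NULL) {
  if (length(results) == 0L) {
    stop("summarize_runs: need at least one result", call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "cmqa_result")))
  rows <- lapply(results, function(r) {
    data.frame(
      variant = r$variant,
      alpha_annealing = r$config$schedule$alpha_annealing,
      map = r$config$chaos$map,
      energy = r$best_energy,
      minutes = r$wall_time / 60,
      drmsd = NA_real_,
      seed = r$seed
    )
  })
  tab <- do.call(rbind, rows)
  if (!is.null(reference)) {
    tab$drmsd <- vapply(results, function(r) {
      inst <- enumerate_variables(sub("^protein\\((.*)\\)$", "\\1", r$label))
      drmsd(build_coordinates(inst, r$best), reference)
    }, numeric(1))
  }
  agg <- stats::aggregate(
    cbind(energy, minutes, drmsd) ~ variant + alpha_annealing + map,
    data = tab, FUN = mean, na.action = stats::na.pass
  )
  counts <- stats::aggregate(seed ~ variant + alpha_annealing + map,
                             data = tab, FUN = length)
  names(agg)[names(agg) == "energy"] <- "mean_energy"
  names(agg)[names(agg) == "minutes"] <- "mean_minutes"
  names(agg)[names(agg) == "drmsd"] <- "mean_drmsd"
  agg$n_runs <- counts$seed
  agg
}
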