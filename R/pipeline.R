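# End-to-end pipeline: manifest -> filter -> composition -> differences ->
# hydropathy classes -> positional profiles, with an optional on-disk result
# bundle and run manifest.

#' Pipeline configuration
#'
#' @param manifest Path to a family manifest (see [read_manifest()]), or
#'   `NULL` when `families` is given directly.
#' @param families Named list of [family_set()] objects (alternative to
#'   `manifest`); names are family labels.
#' @param reference Reference family label for difference profiles
#'   (default `"amine"`).
#' @param alphabet Sequon third-position alphabet, `"stc"` (default) or
#'   `"st"`.
#' @param min_core,max_core Core-length bounds (defaults 270, 401).
#' @param grouping Hydropathy-class grouping, see [hi_class_fractions()].
#' @param typical_length Receptor length for [net_residue_change()]
#'   (default 300).
#' @param residues Residues to profile positionally (default H, M, W).
#' @param outdir Output directory for TSV results and the run manifest, or
#'   `NULL` to keep results in memory only.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(manifest = NULL, families = NULL,
                            reference = "amine",
                            alphabet = c("stc", "st"),
                            min_core = 270L, max_core = 401L,
                            grouping = c("sign_based", "printed"),
                            typical_length = 300,
                            residues = c("H", "M", "W"),
                            outdir = NULL) {
  stopifnot(0 < min_core, min_core <= max_core)
  structure(list(manifest = manifest, families = families,
                 reference = reference, alphabet = match.arg(alphabet),
                 min_core = as.integer(min_core),
                 max_core = as.integer(max_core),
                 grouping = match.arg(grouping),
                 typical_length = typical_length, residues = residues,
                 outdir = outdir),
            class = "run_config")
}

#' Run the whole comparison pipeline
#'
#' For every family in the manifest: extract and filter core regions, then
#' compute the family composition. For every non-reference family: the
#' percent-difference profile versus the reference, its hydropathy-weighted
#' version, hydropathy-class fractions, the class shift versus the reference
#' with its implied net residue change, and anchored positional profiles of
#' the requested residues. Outputs are deterministic for fixed inputs; when
#' `outdir` is set, results are written as TSV plus a JSON run manifest
#' (config echo, input checksums, package version).
#'
#' @param config A [pipeline_config()].
#' @return A result bundle: list with `reports`, `cores`, `compositions`,
#'   `differences`, `class_fractions`, `class_shifts`, `positional`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fams <- config$families
  checksums <- NULL
  if (is.null(fams)) {
    if (is.null(config$manifest)) stop("config needs a manifest or families")
    paths <- read_manifest(config$manifest)
    fams <- lapply(names(paths), function(f) read_family_fasta(paths[[f]], f))
    names(fams) <- names(paths)
    checksums <- vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
  }
  if (!config$reference %in% names(fams)) {
    stop("reference family '", config$reference, "' not among: ",
         paste(names(fams), collapse = ", "))
  }

  filtered <- lapply(fams, filter_family, alphabet = config$alphabet,
                     min_core = config$min_core, max_core = config$max_core)
  reports <- do.call(rbind, lapply(filtered, `[[`, "report"))
  rownames(reports) <- NULL
  cores <- lapply(filtered, `[[`, "cores")
  compositions <- lapply(names(cores), function(f)
    composition_profile(cores[[f]], family = f))
  names(compositions) <- names(cores)

  ref <- compositions[[config$reference]]
  others <- setdiff(names(compositions), config$reference)
  differences <- lapply(others, function(f)
    hydropathy_weight(percent_difference(compositions[[f]], ref)))
  names(differences) <- others

  class_fractions <- do.call(rbind, lapply(compositions, hi_class_fractions,
                                           grouping = config$grouping))
  rownames(class_fractions) <- NULL
  ref_pos <- class_fractions$positive_fraction[class_fractions$family == config$reference]
  class_shifts <- data.frame(
    family = others,
    positive_shift = vapply(others, function(f)
      class_fractions$positive_fraction[class_fractions$family == f] - ref_pos,
      numeric(1)),
    stringsAsFactors = FALSE
  )
  class_shifts$net_residue_change <-
    net_residue_change(class_shifts$positive_shift, config$typical_length)

  positional <- list()
  for (f in names(cores)) {
    for (r in config$residues) {
      positional[[paste(f, r, sep = ".")]] <-
        positional_distribution(cores[[f]], r)
    }
  }

  bundle <- list(reports = reports, cores = cores,
                 compositions = compositions, differences = differences,
                 class_fractions = class_fractions,
                 class_shifts = class_shifts, positional = positional)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_table(reports, file.path(config$outdir, "filter_reports.tsv"))
    comp_tab <- do.call(rbind, lapply(compositions, function(p)
      cbind(family = attr(p, "family"), as.data.frame(p))))
    write_table(comp_tab, file.path(config$outdir, "composition.tsv"))
    diff_tab <- do.call(rbind, lapply(differences, function(d)
      cbind(family = attr(d, "family"), reference = attr(d, "reference"),
            as.data.frame(d))))
    if (!is.null(diff_tab)) {
      write_table(diff_tab, file.path(config$outdir, "differences.tsv"))
    }
    write_table(class_fractions, file.path(config$outdir, "class_fractions.tsv"))
    write_table(class_shifts, file.path(config$outdir, "class_shifts.tsv"))
    pos_tab <- do.call(rbind, lapply(positional, as.data.frame))
    write_table(pos_tab, file.path(config$outdir, "positional_profiles.tsv"))
    manifest <- list(
      config = config[c("reference", "alphabet", "min_core", "max_core",
                        "grouping", "typical_length", "residues")],
      inputs = as.list(checksums),
      n_families = length(fams),
      package_version = as.character(utils::packageVersion("gpcrcore"))
    )
    jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
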