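#' @keywords internal
"_PACKAGE"

#' Full TOCSY-NOESY resonance assignment
#'
#' End-to-end run on in-memory inputs: cluster peaks into spin systems,
#' predict amino-acid types, establish sequential connectivities, map AAIGs
#' onto the sequence by iterated chain/contig consensus, type the TOCSY
#' atoms of every mapped residue, transfer assignments to the NOESY
#' spectrum, and complete missing atoms from common NOEs.
#'
#' @param sequence Character vector of residues (or a single string).
#' @param roots Root peak data frame (`label`, `n15`, `hn`).
#' @param tocsy,noesy 4D peak data frames.
#' @param stats A `stats_library`.
#' @param tol A [tolerances()] object.
#' @param schedule Mapping schedule, see [default_schedule()].
#' @param intensity_threshold,percentile,methylene_tol Common-NOE extension
#'   parameters, see [extend_from_common_noes()].
#' @param extend Run the common-NOE completion step (default `TRUE`).
#' @param verbose Log stage counts with `message()`.
#' @return List of class `assignment_result`: `state` (mapping), `table`
#'   (assignment table), `tocsy_annotations`, `noesy_annotations`,
#'   `predictions`, `connectivities`, `aaig_set`.
#' @export
assign_resonances <- function(sequence, roots, tocsy, noesy, stats,
                              tol = tolerances(),
                              schedule = default_schedule(),
                              intensity_threshold = 0.1, percentile = 80,
                              methylene_tol = 0.2, extend = TRUE,
                              verbose = FALSE) {
  sequence <- to_residues(sequence)
  say <- function(...) if (verbose) message(sprintf(...))
  aaig_set <- cluster_peaks(tocsy, noesy, roots, tol)
  say("clustered: %d AAIGs, %d orphan peaks",
      length(aaig_set$aaigs), nrow(aaig_set$orphans))
  predictions <- predict_all_aaigs(aaig_set, sequence, stats,
                                   methylene_tol = methylene_tol)
  say("typed: %d/%d AAIGs with at least one prediction",
      sum(vapply(predictions, nrow, integer(1)) > 0L), length(predictions))
  connectivities <- compute_connectivities(aaig_set, tol,
                                           min_occupancy = 0.2)
  say("connectivities: %d (occupancy >= 0.2)", nrow(connectivities))
  state <- iterate_mapping(aaig_set, sequence, predictions, connectivities,
                           schedule = schedule, tol = tol, verbose = verbose)
  say("mapped: %d positions", length(state$assigned))
  tocsy_res <- assign_all_tocsy(state, aaig_set, sequence, stats,
                                methylene_tol = methylene_tol)
  table <- build_shift_table(root_entries(state, aaig_set),
                             tocsy_res$entries)
  noesy_annot <- transfer_to_noesy(state, aaig_set, table, sequence, tol)
  say("NOESY transfer: %d peaks labelled", nrow(noesy_annot))
  if (extend) {
    ext <- extend_from_common_noes(state, aaig_set, table, sequence, stats,
                                   annotations = noesy_annot, tol = tol,
                                   intensity_threshold = intensity_threshold,
                                   percentile = percentile,
                                   methylene_tol = methylene_tol)
    table <- build_shift_table(table, ext$entries)
    noesy_annot <- rbind(noesy_annot, ext$annotations)
    say("common-NOE extension: %d new atom assignments",
        sum(ext$entries$nucleus == "13C"))
  }
  structure(list(state = state, table = table,
                 tocsy_annotations = tocsy_res$annotations,
                 noesy_annotations = noesy_annot,
                 predictions = state$predictions,
                 connectivities = state$connectivities,
                 aaig_set = aaig_set),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf(paste0("<assignment_result: %d positions mapped, ",
                     "%d shifts assigned (%d 13C)>\n"),
              length(x$state$assigned), nrow(x$table),
              sum(x$table$nucleus == "13C")))
  invisible(x)
}

#' Write the standard output artifacts of an assignment run
#'
#' XEASY shift table, TSV mapping report (position, residue, AAIG,
#' confidence score, round) and annotated TOCSY/NOESY Sparky lists.
#'
#' @param result An `assignment_result`.
#' @param sequence Residue vector.
#' @param tocsy,noesy The input peak data frames (for annotation rewrite).
#' @param out_dir Output directory.
#' @return Named vector of written paths.
#' @export
write_assignment_outputs <- function(result, sequence, tocsy, noesy,
                                     out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sequence <- to_residues(sequence)
  paths <- c(prot = file.path(out_dir, "assigned_shifts.prot"),
             report = file.path(out_dir, "mapping_report.tsv"),
             tocsy = file.path(out_dir, "tocsy_assigned.list"),
             noesy = file.path(out_dir, "noesy_assigned.list"))
  write_xeasy_shifts(result$table, paths["prot"])
  log <- result$state$log
  report <- data.frame(position = log$position,
                       residue = sequence[log$position],
                       aaig = log$aaig, cs = sprintf("%.6g", log$cs),
                       round = log$round, stringsAsFactors = FALSE)
  report <- report[order(report$position), ]
  utils::write.table(report, paths["report"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tocsy))
    write_assigned_peaklists(tocsy, result$tocsy_annotations, paths["tocsy"])
  if (!is.null(noesy))
    write_assigned_peaklists(noesy, result$noesy_annotations, paths["noesy"])
  paths
}

#' Run the pipeline from a declarative configuration
#'
#' File-level entry point used by the command-line script.  Modes:
#' `simulate` (write synthetic peak lists), `assign` (TOCSY-NOESY
#' assignment), `assign-noesy-only`, and `evaluate` (score an XEASY table
#' plus mapping report against simulated truth).
#'
#' @param config Named list: `mode`, file paths (`fasta`, `roots`, `tocsy`,
#'   `noesy`, `nh_table`, `out_dir`), `seed`, `n_residues`, and optional
#'   threshold overrides (`tol_*`, `intensity_threshold`, `percentile`,
#'   `methylene_tol`).
#' @return Invisibly, the mode's primary result object.
#' @export
run_pipeline <- function(config) {
  mode <- config$mode
  if (is.null(mode) ||
      !mode %in% c("simulate", "assign", "assign-noesy-only", "evaluate"))
    stop("config$mode must be one of simulate, assign, assign-noesy-only, evaluate")
  grab <- function(name, default) {
    v <- config[[name]]
    if (is.null(v)) default else v
  }
  tol <- tolerances(tol_hn = grab("tol_hn", 0.04),
                    tol_n15 = grab("tol_n15", 0.2),
                    tol_h = grab("tol_h", 0.04),
                    tol_c = grab("tol_c", 0.4))
  stats <- default_stats_library(seed = grab("stats_seed", 1234))
  out_dir <- grab("out_dir", ".")
  need <- function(key) {
    if (is.null(config[[key]])) stop("missing required input: ", key)
    v <- config[[key]]
    if (is.character(v) && !file.exists(v))
      stop("missing required input: ", key, " (no such file: ", v, ")")
    v
  }
  if (mode == "simulate") {
    sc <- synthetic_config(n_residues = grab("n_residues", 120L),
                           seed = grab("seed", 1L))
    ds <- simulate_dataset(sc, stats)
    paths <- write_synthetic_dataset(ds, out_dir)
    message("simulated ", length(ds$sequence), " residues -> ", out_dir)
    return(invisible(ds))
  }
  if (mode == "assign") {
    sequence <- read_fasta_sequence(need("fasta"))
    roots <- read_sparky_peaks(need("roots"), axis_order = c("n15", "hn"))
    tocsy <- read_sparky_peaks(need("tocsy"))
    noesy <- read_sparky_peaks(need("noesy"))
    res <- assign_resonances(sequence, roots, tocsy, noesy, stats,
                             tol = tol,
                             intensity_threshold = grab("intensity_threshold", 0.1),
                             percentile = grab("percentile", 80),
                             methylene_tol = grab("methylene_tol", 0.2),
                             verbose = TRUE)
    write_assignment_outputs(res, sequence, tocsy, noesy, out_dir)
    return(invisible(res))
  }
  if (mode == "assign-noesy-only") {
    sequence <- read_fasta_sequence(need("fasta"))
    noesy <- read_sparky_peaks(need("noesy"))
    nh <- utils::read.delim(need("nh_table"), stringsAsFactors = FALSE)
    res <- run_noesy_only(sequence, nh, noesy, stats, tol = tol,
                          intensity_threshold = grab("intensity_threshold", 0.1),
                          percentile = grab("percentile", 80),
                          methylene_tol = grab("methylene_tol", 0.2))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_xeasy_shifts(res$table,
                       file.path(out_dir, "assigned_shifts.prot"))
    return(invisible(res))
  }
  # evaluate: re-simulate the truth from the seed and score a .prot table
  sc <- synthetic_config(n_residues = grab("n_residues", 120L),
                         seed = grab("seed", 1L))
  ds <- simulate_dataset(sc, stats)
  prot <- read_xeasy_shifts(need("prot"))
  prot$nucleus <- nucleus_of(prot$atom)
  prot$provenance <- "TOCSY"
  metrics <- evaluate_assignments(prot, NULL, ds$truth)
  invisible(metrics)
}
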