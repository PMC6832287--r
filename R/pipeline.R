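#' Pipeline configuration
#'
#' @param scoring an [scoring_scheme()].
#' @param conservation_threshold modal-frequency threshold for
#'   [conserved_positions()].
#' @param include_moderate count moderately flexible residues as flexible in
#'   percent-flexibility summaries.
#' @return a named list of class `s1_config`.
#' @export
pipeline_config <- function(scoring = scoring_scheme(),
                            conservation_threshold = 0.8,
                            include_moderate = FALSE) {
  structure(list(scoring = scoring,
                 conservation_threshold = conservation_threshold,
                 include_moderate = include_moderate),
            class = "s1_config")
}

#' Fetch registry structures from the RCSB PDB
#'
#' The single networked step of the pipeline: downloads each registry entry
#' as `<pdb_id>.pdb` into `dir`, skipping files already present. Everything
#' else in the package runs offline.
#'
#' @param reg an `s1_registry`.
#' @param dir destination directory (created if needed).
#' @param base_url download endpoint.
#' @param timeout per-file timeout, seconds.
#' @return character vector of file paths, invisibly.
#' @export
fetch_structures <- function(reg, dir,
                             base_url = "https://files.rcsb.org/download",
                             timeout = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(reg$pdb_id)
  old <- options(timeout = timeout); on.exit(options(old))
  failed <- character(0)
  for (id in ids) {
    dest <- file.path(dir, paste0(id, ".pdb"))
    if (file.exists(dest)) next
    url <- sprintf("%s/%s.pdb", base_url, toupper(id))
    ok <- tryCatch({
      suppressWarnings(utils::download.file(url, dest, quiet = TRUE,
                                            mode = "wb"))
      TRUE
    }, error = function(e) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      failed <- c(failed, id)
    }
  }
  if (length(failed)) {
    stop("failed to fetch PDB entr", if (length(failed) > 1) "ies: " else "y: ",
         paste(failed, collapse = ", "))
  }
  invisible(file.path(dir, paste0(ids, ".pdb")))
}

#' Run the full comparative pipeline over a registry
#'
#' Parses and slices every registry domain, then computes: identity matrices
#' (global and per kingdom) with same-protein-excluded extrema; RMSD
#' matrices with per-group means; radii of gyration with per-kingdom means;
#' flexibility summaries (B-factor z-scores, plus predicted fluctuation
#' tables when `fluct_dir` provides `<pdb_id>.flex` files); order/disorder
#' composition with min/max; Kruskal-Wallis cross-kingdom tests on Rg and
#' percent flexibility; per-kingdom multiple alignments with conserved
#' positions and logo matrices; and a UPGMA dendrogram from global identity
#' distances. Deterministic given inputs and configuration.
#'
#' @param reg an `s1_registry`.
#' @param structure_dir directory holding `<pdb_id>.pdb` files (see
#'   [fetch_structures()]).
#' @param config an [pipeline_config()].
#' @param fluct_dir optional directory of per-entry predicted fluctuation
#'   tables (`<pdb_id>.flex`, two-column text).
#' @return an object of class `s1_report`.
#' @export
run_pipeline <- function(reg, structure_dir, config = pipeline_config(),
                         fluct_dir = NULL) {
  stopifnot(inherits(reg, "s1_registry"), inherits(config, "s1_config"))
  if (nrow(reg) == 0) stop("empty registry")
  files <- file.path(structure_dir, paste0(reg$pdb_id, ".pdb"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing structure file(s): ",
         paste(unique(reg$pdb_id[missing]), collapse = ", "))
  }
  sc <- config$scoring
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  entries <- reg$pdb_id
  domains <- vector("list", nrow(reg)); names(domains) <- entries
  for (i in seq_len(nrow(reg))) {
    s <- read_pdb(files[i], reg$chain[i])
    domains[[i]] <- slice_domain(s, reg$start[i], reg$end[i])
    len <- nrow(domains[[i]]$residues)
    if (len < 40 || len > 120) {
      note("%s: domain length %d outside the expected 60-90 band", entries[i], len)
    }
  }
  seqs <- vapply(domains, domain_sequence, character(1))
  excl <- same_protein_pairs(reg)
  part <- kingdom_partition(reg)

  identity <- list(global = identity_matrix(seqs, sc, groups = excl))
  rmsd <- list(global = multiple_superpose(domains, sc))
  msa <- list(); conserved <- list(); logos <- list()
  for (k in names(part)) {
    ids <- part[[k]]$pdb_id
    if (length(ids) >= 2) {
      identity[[k]] <- identity_matrix(seqs[ids], sc, groups = excl[ids, ids])
      rmsd[[k]] <- multiple_superpose(domains[ids], sc)
      msa[[k]] <- progressive_msa(seqs[ids], sc)
      logos[[k]] <- logo_information(msa[[k]])
      conserved[[k]] <- conserved_positions(msa[[k]],
                                            config$conservation_threshold)
    } else if (length(ids) == 1) {
      note("kingdom %s has a single entry; no within-kingdom comparisons", k)
    }
  }

  rg <- vapply(domains, radius_of_gyration, numeric(1))
  rg_table <- data.frame(entry = entries, kingdom = reg$kingdom,
                         rg = unname(rg), stringsAsFactors = FALSE)
  rg_groups <- lapply(part, function(p) unname(rg[p$pdb_id]))
  rg_groups <- rg_groups[vapply(rg_groups, length, 1L) > 0]
  kw <- list()
  kw$rg <- tryCatch(kruskal_wallis(rg_groups),
                    error = function(e) { note("KW on Rg: %s", conditionMessage(e)); NULL })

  flex_rows <- list()
  for (i in seq_len(nrow(reg))) {
    id <- entries[i]
    prof <- tryCatch(bfactor_zscores(domains[[i]]), error = function(e) {
      note("%s: %s", id, conditionMessage(e)); NULL
    })
    if (!is.null(prof)) {
      flex_rows[[length(flex_rows) + 1L]] <- data.frame(
        entry = id, kingdom = reg$kingdom[i], source = "bfactor",
        percent_flexible = percent_flexible(prof$labels,
                                            config$include_moderate),
        stringsAsFactors = FALSE)
    }
    if (!is.null(fluct_dir)) {
      f <- file.path(fluct_dir, paste0(id, ".flex"))
      if (file.exists(f)) {
        vals <- read_fluctuation_table(f, expected_length = nchar(seqs[[id]]))
        if (!is.null(attr(vals, "warning"))) note("%s: %s", id, attr(vals, "warning"))
        pf <- flex_profile(unname(vals), names(vals), source = "predicted")
        flex_rows[[length(flex_rows) + 1L]] <- data.frame(
          entry = id, kingdom = reg$kingdom[i], source = "predicted",
          percent_flexible = percent_flexible(pf$labels,
                                              config$include_moderate),
          stringsAsFactors = FALSE)
      }
    }
  }
  flex_table <- if (length(flex_rows)) do.call(rbind, flex_rows) else
    data.frame(entry = character(0), kingdom = character(0),
               source = character(0), percent_flexible = numeric(0))
  for (src in unique(flex_table$source)) {
    sub <- flex_table[flex_table$source == src, ]
    gr <- split(sub$percent_flexible, sub$kingdom)
    gr <- gr[vapply(gr, length, 1L) > 0]
    if (length(gr) >= 2) {
      kw[[paste0("flex_", src)]] <- tryCatch(kruskal_wallis(gr),
        error = function(e) { note("KW on %s flexibility: %s", src,
                                   conditionMessage(e)); NULL })
    }
  }

  comp <- data.frame(entry = entries, kingdom = reg$kingdom,
                     disorder_pct = vapply(seqs, disorder_content, numeric(1)),
                     stringsAsFactors = FALSE)

  tree <- upgma_tree(distance_from_identity(identity$global))

  structure(list(
    registry = reg, config = config, identity = identity, rmsd = rmsd,
    msa = msa, logos = logos, conserved = conserved, rg = rg_table,
    rg_kingdom_means = vapply(split(rg_table$rg, rg_table$kingdom), mean,
                              numeric(1)),
    flexibility = flex_table, composition = comp,
    composition_range = c(min = min(comp$disorder_pct),
                          max = max(comp$disorder_pct)),
    kruskal_wallis = kw, tree = tree, warnings = warnings_log
  ), class = "s1_report")
}

#' @export
print.s1_report <- function(x, ...) {
  cat("<s1_report>", nrow(x$registry), "domains\n")
  cat(sprintf("  identity: max %.0f%% (%s), min %.0f%% (%s)\n",
              x$identity$global$max$value,
              paste(x$identity$global$max$pair, collapse = "-"),
              x$identity$global$min$value,
              paste(x$identity$global$min$pair, collapse = "-")))
  cat(sprintf("  mean pairwise RMSD: %.2f A\n", x$rmsd$global$mean))
  cat(sprintf("  mean Rg: %.2f A\n", mean(x$rg$rg)))
  cat(sprintf("  disorder-promoting content: %.0f-%.0f%%\n",
              x$composition_range[["min"]], x$composition_range[["max"]]))
  if (!is.null(x$kruskal_wallis$rg)) {
    cat(sprintf("  KW (Rg by kingdom): H = %.3f, p = %.4f\n",
                x$kruskal_wallis$rg$H, x$kruskal_wallis$rg$p))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n"); for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Emits TSVs (unrounded numbers), the Newick tree and a human-readable
#' summary (identities rounded to whole percent, RMSD/Rg to 0.01 A).
#'
#' @param report an `s1_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE,
                                     row.names = is.matrix(x),
                                     col.names = NA)
  for (k in names(report$identity)) {
    wtsv(report$identity[[k]]$matrix, sprintf("identity_%s.tsv", k))
  }
  for (k in names(report$rmsd)) {
    wtsv(report$rmsd[[k]]$matrix, sprintf("rmsd_%s.tsv", k))
  }
  write.table(report$rg, file.path(dir, "rg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$flexibility, file.path(dir, "flexibility.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$composition, file.path(dir, "composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in names(report$logos)) {
    write_logo_tsv(report$logos[[k]], file.path(dir, sprintf("logo_%s.tsv", k)))
  }
  write_newick(report$tree, file.path(dir, "tree.nwk"))
  con <- file(file.path(dir, "summary.txt"), "w"); on.exit(close(con))
  sink(con); print(report); sink()
  invisible(dir)
}
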