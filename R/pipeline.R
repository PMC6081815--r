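## Orchestration: the viral-ecology and marker-profiling pipelines over a
## declarative config, plus a fully synthetic demo with truth recovery.

#' Default pipeline configuration
#'
#' All thresholds default to the analysis' standard values: vOTU pool
#' > 5000 bp, 95\% ANI over 80\% aligned fraction, presence at >= 75\%
#' breadth; prophage screen at qcov 0.75 / identity 70 / bits 50 /
#' e <= 0.001; spacer matching at <= 1 mismatch; d2* <= 0.2; Markov links
#' at p < 0.001 with LCA over the best 5 hits; marker length minima
#' DsrA 302 / DsrD 57 / McrA 150 aa.
#'
#' @param input_dir directory holding the input files (as written by
#'   \code{\link{writeCommunity}}); path entries may be edited freely.
#' @return nested configuration list.
#' @export
defaultConfig <- function(input_dir = ".") {
  fp <- function(x) file.path(input_dir, x)
  list(
    paths = list(viruses = fp("viruses.fasta"), hosts = fp("hosts.fasta"),
                 placements = fp("placements.tsv"), totals = fp("totals.tsv"),
                 taxonomy = fp("host_taxonomy.tsv"),
                 marker_hits = fp("marker_hits.tsv"),
                 annotations = fp("gene_annotations.tsv"),
                 samples = fp("samples.tsv"), geochem = fp("geochem.tsv")),
    votu = list(min_len = 5000, ani_min = 0.95, af_min = 0.80,
                breadth_min = 0.75),
    linkage = list(min_qcov = 0.75, min_id = 70, min_bits = 50,
                   max_e = 0.001, spacer_max_mismatch = 1,
                   d2star_max = 0.2, d2star_k = 6, d2star_order = 2,
                   markov_order = 8, markov_p_max = 0.001,
                   markov_n_best = 5),
    markers = list(min_len = list(dsrA = 302, dsrD = 57, mcrA = 150)),
    stats = list(n_perm = 999, nmds_starts = 20, n_boot = 1000,
                 support_min = 0.95, alpha = 0.05),
    seed = 1)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param file YAML path.
#' @return the configuration list.
#' @export
readConfig <- function(file) yaml::read_yaml(file)

#' @rdname readConfig
#' @param config configuration list.
#' @export
writeConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

stageLog <- function(stage, ...) message("[", stage, "] ", ...)

writeTSV <- function(d, path, rownames = FALSE) {
  if (rownames)
    write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  else
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

finishManifest <- function(outdir) {
  files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                   file.path(outdir, "MANIFEST.tsv"))
  writeTSV(data.frame(file = sub(paste0("^", outdir, "/?"), "", files),
                      md5 = unname(tools::md5sum(files))),
           file.path(outdir, "MANIFEST.tsv"))
}

#' Run the viral ecology pipeline
#'
#' Stages: vOTU clustering, breadth-gated abundance table and per-sample
#' summaries, four-evidence host linkage, AMG screen, and community
#' statistics (NMDS, PERMANOVA by wetland, Procrustes of the viral against
#' the microbial ordination, Hellinger + RDA with forward selection on the
#' geochemistry, geochemistry PCA).  Each stage logs its in/out counts so
#' filtering funnels can be audited.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param outdir output directory.
#' @return invisibly, a list with the main result objects.
#' @export
runViralPipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  seed <- as.integer(config$seed %||% 1L)

  viruses <- Biostrings::readDNAStringSet(config$paths$viruses)
  pset <- readPlacementsTSV(config$paths$placements, config$paths$totals)
  stageLog("input", length(viruses), " viral contigs, ",
           length(placements(pset)), " placements, ",
           length(sampleTotals(pset)), " samples")

  ## --- vOTU clustering
  cl <- clusterVOTUs(viruses, min_len = config$votu$min_len,
                     ani_min = config$votu$ani_min,
                     af_min = config$votu$af_min)
  n_votu <- length(unique(cl$votus$seed_id))
  stageLog("cluster", nrow(cl$votus), " contigs > ", config$votu$min_len,
           " bp -> ", n_votu, " vOTUs (", length(cl$short),
           " short contigs excluded)")
  writeTSV(cl$votus, fp("votu_membership.tsv"))

  ## --- abundance table
  contig_len <- setNames(Biostrings::width(viruses), names(viruses))
  vt <- buildVOTUTable(cl, pset, contig_len,
                       breadth_min = config$votu$breadth_min)
  stageLog("table", sum(presenceMatrix(vt)), " present cells of ",
           length(presenceMatrix(vt)))
  writeTSV(as.data.frame(rpkmMatrix(vt)), fp("votu_table.tsv"), rownames = TRUE)
  summ <- summarizeSamples(vt)
  writeTSV(summ, fp("sample_summary.tsv"))

  ## --- host linkage
  links <- NULL
  if (!is.null(config$paths$hosts) && file.exists(config$paths$hosts)) {
    hosts <- Biostrings::readDNAStringSet(config$paths$hosts)
    tax <- if (!is.null(config$paths$taxonomy) &&
               file.exists(config$paths$taxonomy))
      readTaxonomyTSV(config$paths$taxonomy) else
      setNames(rep(NA_character_, length(hosts)), names(hosts))
    lk <- config$linkage
    hits <- if (!is.null(config$paths$blast_table) &&
                file.exists(config$paths$blast_table %||% ""))
      readAlignmentTable(config$paths$blast_table,
                         setNames(Biostrings::width(viruses), names(viruses)))
    else scanProphagesExact(viruses, hosts)
    bl <- screenProphageHits(hits, min_qcov = lk$min_qcov, min_id = lk$min_id,
                             min_bits = lk$min_bits, max_e = lk$max_e)
    stageLog("prophage", nrow(hits), " hits -> ", nrow(bl), " links")
    arrays <- unlist(lapply(seq_along(hosts), function(i)
      detectCrisprArrays(hosts[i])), recursive = FALSE)
    cr <- if (length(arrays))
      matchSpacers(arrays, viruses, max_mismatch = lk$spacer_max_mismatch)
    else data.frame(virus_id = character(), host_id = character(),
                    method = character(), score = numeric(),
                    passed = logical())
    stageLog("crispr", length(arrays), " arrays -> ", nrow(cr),
             " spacer links")
    if (length(arrays))
      writeTSV(do.call(rbind, lapply(arrays, function(a)
        data.frame(host_id = a$host_id, repeat_consensus = a$repeat_consensus,
                   n_spacers = nrow(a$spacers), span_start = a$array_span[1],
                   span_end = a$array_span[2]))), fp("crispr_arrays.tsv"))
    d2 <- linkByD2Star(viruses, hosts, threshold = lk$d2star_max,
                       k = lk$d2star_k, background_order = lk$d2star_order)
    stageLog("d2star", sum(d2$passed), " of ", nrow(d2), " pairs <= ",
             lk$d2star_max)
    models <- lapply(seq_along(hosts), function(i)
      trainMarkovModel(hosts[i], order = lk$markov_order,
                       taxonomy = unname(tax[names(hosts)[i]])))
    mk <- scoreAndLinkMarkov(viruses, models, p_max = lk$markov_p_max,
                             n_best = lk$markov_n_best)
    stageLog("markov", sum(mk$passed), " of ", nrow(mk), " viruses at p < ",
             lk$markov_p_max)
    links <- integrateLinks(list(bl, cr, d2, mk))
    stageLog("integrate", nrow(links), " virus-host pairs")
    writeTSV(links, fp("links.tsv"))
  }

  ## --- AMG screen
  amg <- NULL
  if (!is.null(config$paths$annotations) &&
      file.exists(config$paths$annotations)) {
    ann <- read.delim(config$paths$annotations, stringsAsFactors = FALSE)
    amg <- screenMetabolicGenes(ann)
    stageLog("amg", nrow(ann), " genes -> ", nrow(amg), " candidate AMGs")
    writeTSV(amg, fp("amg_report.tsv"))
  }

  ## --- community statistics
  stats_out <- list()
  ab <- t(rpkmMatrix(vt))                      # samples x vOTUs
  keep <- rowSums(ab) > 0
  ab <- ab[keep, , drop = FALSE]
  if (nrow(ab) >= 4 && ncol(ab) >= 2) {
    bc <- brayCurtis(ab)
    nm <- nmdsOrdination(bc, n_starts = config$stats$nmds_starts, seed = seed)
    writeTSV(as.data.frame(nm$coordinates), fp("nmds_viral.tsv"),
             rownames = TRUE)
    stats_out$nmds_stress <- nm$stress
    meta <- read.delim(config$paths$samples, stringsAsFactors = FALSE)
    meta <- meta[match(rownames(ab), meta$sample_id), ]
    if (length(unique(meta$wetland)) > 1) {
      pm <- permanova(bc, meta$wetland, n_perm = config$stats$n_perm,
                      seed = seed)
      stats_out$permanova_wetland <- pm[c("statistic", "R2", "p_value",
                                          "n_permutations")]
      stageLog("stats", sprintf("PERMANOVA wetland: F = %.3f, p = %.4g",
                                pm$statistic, pm$p_value))
    }
    geo <- as.matrix(read.delim(config$paths$geochem, row.names = 1))
    geo <- geo[rownames(ab), , drop = FALSE]
    gp <- pcaOrdination(geo)
    writeTSV(as.data.frame(gp$coordinates), fp("pca_geochem.tsv"),
             rownames = TRUE)
    stats_out$geochem_pc1_var <- gp$variance_explained[1]
    pr <- procrustesProtest(gp$coordinates[, 1:2], nm$coordinates,
                            n_perm = config$stats$n_perm, seed = seed)
    stats_out$procrustes <- pr[c("correlation", "m2", "p_value")]
    rda <- tryCatch(
      rdaForwardSelect(hellinger(ab), geo, alpha = config$stats$alpha,
                       n_perm = config$stats$n_perm, seed = seed),
      error = function(e) {
        stageLog("stats", "RDA skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(rda))
      stats_out$rda <- list(global_p = rda$global$p,
                            selected = as.list(rda$selected),
                            adj_r2 = rda$adj_r2)
    yaml::write_yaml(stats_out, fp("stats.yaml"))
  }
  finishManifest(outdir)
  invisible(list(clusters = cl, table = vt, summary = summ, links = links,
                 amg = amg, stats = stats_out))
}

#' Run the marker-gene guild pipeline
#'
#' Stages: protein-length/direction filtering, per-contig RPKM matrix,
#' per-sample Shannon diversity per marker with a paired wetland test,
#' bootstrap-supported heatmap clustering of dsrD-containing contigs,
#' rank-abundance curves per wetland, PERMANOVA by wetland.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}).
#' @param outdir output directory.
#' @return invisibly, a list with the main result objects.
#' @export
runMarkerPipeline <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  seed <- as.integer(config$seed %||% 1L)
  hits <- read.delim(config$paths$marker_hits, stringsAsFactors = FALSE)
  min_len <- unlist(config$markers$min_len)
  filt <- filterMarkerHits(hits, min_len = min_len)
  dropped <- setdiff(hits$gene_id, filt$gene_id)
  stageLog("filter", nrow(hits), " hits -> ", nrow(filt), " retained (",
           length(dropped), " removed: ",
           paste(head(dropped, 5), collapse = ", "),
           if (length(dropped) > 5) ", ..." else "", ")")
  pset <- readPlacementsTSV(config$paths$placements, config$paths$totals)
  lens <- local({
    hset <- Biostrings::readDNAStringSet(config$paths$hosts)
    setNames(Biostrings::width(hset), names(hset))
  })
  mm <- buildMarkerMatrix(filt, pset, lens)
  writeTSV(as.data.frame(mm$rpkm), fp("marker_matrix.tsv"), rownames = TRUE)

  meta <- read.delim(config$paths$samples, stringsAsFactors = FALSE)
  meta <- meta[match(rownames(mm$rpkm), meta$sample_id), ]
  div <- do.call(rbind, lapply(unique(mm$marker), function(mk) {
    cols <- names(mm$marker)[mm$marker == mk]
    data.frame(sample_id = rownames(mm$rpkm), marker = mk,
               shannon = apply(mm$rpkm[, cols, drop = FALSE], 1, function(r)
                 if (all(r == 0)) NA_real_ else shannonDiversity(r)),
               stringsAsFactors = FALSE)
  }))
  writeTSV(div, fp("diversity.tsv"))
  tests <- NULL
  for (mk in unique(div$marker)) {
    d <- div[div$marker == mk, ]
    h1 <- d$shannon[meta$wetland == "P7"]; h2 <- d$shannon[meta$wetland == "P8"]
    if (length(h1) == length(h2) && length(h1) >= 2 &&
        !anyNA(c(h1, h2)) && any(h1 != h2)) {
      tt <- pairedTTest(h1, h2)
      tests <- rbind(tests, data.frame(marker = mk, t = tt$t, df = tt$df,
                                       p = tt$p))
    }
  }
  if (!is.null(tests)) writeTSV(tests, fp("paired_tests.tsv"))

  dsrd <- names(mm$marker)[mm$marker == "dsrD"]
  if (length(dsrd) >= 2) {
    dw <- clusterHeatmap(mm$rpkm[, dsrd, drop = FALSE],
                         n_boot = config$stats$n_boot,
                         support_min = config$stats$support_min, seed = seed)
    writeLines(supportNewick(dw), fp("dsrd_dendrogram.nwk"))
    stageLog("heatmap", length(dsrd), " dsrD contigs; ",
             sum(dw@support >= dw@support_min), " supported branches")
  }
  writeTSV(rankAbundance(mm$rpkm, setNames(meta$wetland, meta$sample_id)),
           fp("rank_abundance.tsv"))
  pm <- permanova(brayCurtis(mm$rpkm[rowSums(mm$rpkm) > 0, , drop = FALSE]),
                  meta$wetland[rowSums(mm$rpkm) > 0],
                  n_perm = config$stats$n_perm, seed = seed)
  yaml::write_yaml(list(permanova_wetland = pm[c("statistic", "R2",
                                                 "p_value")]),
                   fp("stats.yaml"))
  finishManifest(outdir)
  invisible(list(filtered = filt, matrix = mm, diversity = div,
                 tests = tests, permanova = pm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end synthetic demo
#'
#' Generates a synthetic sediment community with recorded ground truth,
#' writes it to \code{outdir/input}, runs both pipelines, and scores truth
#' recovery (precision/recall of every linkage method) into
#' \code{outdir/truth_recovery.tsv}.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param ... passed to \code{\link{makeCommunity}}.
#' @return invisibly, a list with the community, pipeline results and the
#'   recovery report.
#' @export
virolinkDemo <- function(outdir, seed = 1L, ...) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  comm <- makeCommunity(seed = seed, ...)
  writeCommunity(comm, file.path(outdir, "input"))
  config <- defaultConfig(file.path(outdir, "input"))
  config$seed <- seed
  writeConfig(config, file.path(outdir, "config.yaml"))
  viral <- runViralPipeline(config, file.path(outdir, "viral"))
  markers <- runMarkerPipeline(config, file.path(outdir, "markers"))
  recovery <- linkRecovery(viral$links, comm$truth)
  writeTSV(recovery, file.path(outdir, "truth_recovery.tsv"))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  stageLog("demo", sprintf("completed in %.1f s", elapsed))
  invisible(list(community = comm, viral = viral, markers = markers,
                 recovery = recovery, elapsed_sec = elapsed))
}
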