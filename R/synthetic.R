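## Synthetic sediment-community generator.  Everything downstream of
## assembly/binning is exercised on these inputs: host genomes carrying
## prophages and CRISPR arrays, families of mutated viral contigs, read
## placements whose depth tracks a designed abundance matrix, marker-gene
## tables and a geochemistry matrix with between-wetland effects.  Every
## construction records its ground truth so recovery can be scored.

#' Generate a random genome or contig
#'
#' Order-0 sequences are i.i.d. with P(G) = P(C) = gc/2.  For Markov orders
#' 1-2 each context receives its own conditional distribution, obtained by
#' gamma-perturbing the order-0 base probabilities, so composition varies by
#' context while the expected GC stays close to \code{gc}.
#'
#' @param length_bp sequence length (>= 100).
#' @param gc target GC fraction, in (0, 1).
#' @param markov_order 0, 1 or 2.
#' @param seed integer seed (generation is deterministic given the seed).
#' @param id sequence name.
#' @param role \code{"viral"} or \code{"host"}.
#' @return a named length-1 \code{DNAStringSet} with \code{role} metadata.
#' @export
makeGenome <- function(length_bp, gc = 0.5, markov_order = 0L, seed = 1L,
                       id = "seq1", role = "host") {
  if (!is.numeric(length_bp) || length_bp < 100)
    stop("length_bp must be >= 100")
  stopifnotScalarFraction(gc, "gc")
  stopifnot(markov_order %in% 0:2)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- withSeed(seed, {
    if (markov_order == 0L) {
      paste(sample(DNA_BASES, length_bp, replace = TRUE, prob = base_p),
            collapse = "")
    } else {
      m <- as.integer(markov_order)
      n_ctx <- 4L^m
      trans <- matrix(rgamma(4L * n_ctx, shape = 20 * rep(base_p, each = n_ctx)),
                      nrow = n_ctx)
      trans <- trans / rowSums(trans)
      out <- integer(length_bp)
      out[seq_len(m)] <- sample.int(4L, m, replace = TRUE, prob = base_p)
      pow <- 4L^(seq_len(m) - 1L)
      u <- runif(length_bp)
      for (i in (m + 1L):length_bp) {
        ctx <- sum((out[(i - m):(i - 1L)] - 1L) * rev(pow)) + 1L
        out[i] <- findInterval(u[i], cumsum(trans[ctx, ]),
                               rightmost.closed = TRUE) + 1L
      }
      paste(DNA_BASES[out], collapse = "")
    }
  })
  asRecord(seq, id, role = role)
}

#' Mutate a sequence by substitutions and indels
#'
#' Substitutions always change the base, so the realized Hamming divergence
#' tracks the nominal rate (no silent substitutions).  Indels insert or
#' delete single bases with equal probability.
#'
#' @param rec sequence (character, \code{DNAString} or 1-sequence
#'   \code{DNAStringSet}).
#' @param sub_rate,indel_rate per-base rates in [0, 0.5).
#' @param seed integer seed.
#' @param id name of the mutated record.
#' @return a named length-1 \code{DNAStringSet}.
#' @export
mutateSequence <- function(rec, sub_rate, indel_rate = 0, seed = 1L,
                           id = NULL) {
  if (sub_rate < 0 || sub_rate >= 0.5 || indel_rate < 0 || indel_rate >= 0.5)
    stop("mutation rates must lie in [0, 0.5)")
  role <- if (is(rec, "DNAStringSet") && !is.null(S4Vectors::mcols(rec)$role))
    S4Vectors::mcols(rec)$role[1] else "viral"
  if (is.null(id))
    id <- paste0(if (is(rec, "DNAStringSet")) names(rec)[1] else "seq", "_mut")
  x <- strsplit(asSequenceChar(rec), "", fixed = TRUE)[[1]]
  out <- withSeed(seed, {
    n <- length(x)
    if (sub_rate > 0) {
      hit <- which(runif(n) < sub_rate)
      if (length(hit)) {
        repl <- vapply(x[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
        x[hit] <- repl
      }
    }
    if (indel_rate > 0) {
      ind <- which(runif(length(x)) < indel_rate)
      if (length(ind)) {
        del <- runif(length(ind)) < 0.5
        pieces <- as.list(x)
        for (i in ind[del]) pieces[[i]] <- character(0)        # deletion
        for (i in ind[!del]) pieces[[i]] <- c(x[i], sample(DNA_BASES, 1L))
        x <- unlist(pieces, use.names = FALSE)
      }
    }
    paste(x, collapse = "")
  })
  asRecord(out, id, role = role)
}

#' Implant a prophage into a host genome
#'
#' Inserts the full viral sequence verbatim at \code{position} (0-based
#' offset into the host).  The returned truth row records the link.
#'
#' @param host,virus sequences (1-sequence \code{DNAStringSet}s).
#' @param position 0-based insertion offset, within [0, host length].
#' @return list with \code{host} (modified record) and \code{truth}
#'   (data.frame: virus_id, host_id, insert_start).
#' @export
implantProphage <- function(host, virus, position) {
  h <- asSequenceChar(host); v <- asSequenceChar(virus)
  if (position < 0 || position > nchar(h)) stop("position out of bounds")
  newseq <- paste0(substr(h, 1, position), v,
                   substr(h, position + 1, nchar(h)))
  out <- asRecord(newseq, names(host)[1], role = "host",
                  taxonomy = S4Vectors::mcols(host)$taxonomy[1])
  list(host = out,
       truth = data.frame(virus_id = names(virus)[1], host_id = names(host)[1],
                          insert_start = position, stringsAsFactors = FALSE))
}

#' Implant a CRISPR array into a host genome
#'
#' Builds repeat-spacer-repeat-...-repeat with \code{n_spacers} spacers and
#' \code{n_spacers + 1} identical copies of a random direct repeat; each
#' spacer is copied verbatim from a (randomly chosen) source virus.
#'
#' @param host host record.
#' @param viruses \code{DNAStringSet} of source viruses.
#' @param n_spacers number of spacers (>= 3).
#' @param repeat_len direct-repeat length, 21-48 bp.
#' @param spacer_len spacer length, 20-50 bp.
#' @param position 0-based insertion offset.
#' @param seed integer seed.
#' @return list with \code{host}, \code{truth} (virus_id, host_id,
#'   spacer_seq) and \code{repeat_seq}.
#' @export
implantCrisprArray <- function(host, viruses, n_spacers = 4L, repeat_len = 28L,
                               spacer_len = 32L, position = 0L, seed = 1L) {
  stopifnot(n_spacers >= 3, repeat_len >= 21, repeat_len <= 48,
            spacer_len >= 20, spacer_len <= 50)
  h <- asSequenceChar(host)
  if (position < 0 || position > nchar(h)) stop("position out of bounds")
  if (any(Biostrings::width(viruses) < spacer_len))
    stop("all source viruses must be at least spacer_len long")
  withSeed(seed, {
    rep_seq <- paste(sample(DNA_BASES, repeat_len, replace = TRUE), collapse = "")
    src <- sample(length(viruses), n_spacers, replace = length(viruses) < n_spacers)
    spacers <- vapply(src, function(i) {
      vs <- as.character(viruses[[i]])
      at <- sample.int(nchar(vs) - spacer_len + 1L, 1L)
      substr(vs, at, at + spacer_len - 1L)
    }, character(1))
    array_seq <- paste0(rep_seq,
                        paste0(spacers, rep_seq, collapse = ""))
    newseq <- paste0(substr(h, 1, position), array_seq,
                     substr(h, position + 1, nchar(h)))
    list(host = asRecord(newseq, names(host)[1], role = "host",
                         taxonomy = S4Vectors::mcols(host)$taxonomy[1]),
         truth = data.frame(virus_id = names(viruses)[src],
                            host_id = names(host)[1],
                            spacer_seq = spacers, stringsAsFactors = FALSE),
         repeat_seq = rep_seq)
  })
}

#' Simulate read placements at designed depths
#'
#' For each (sample, contig) cell of \code{design}, draws a Poisson number
#' of reads with mean depth * contig_length / read_len and places them
#' uniformly at random (fully inside the contig).  Stands in for read
#' mapping so the abundance pipeline can be tested against an analytic
#' expectation.
#'
#' @param contigs \code{DNAStringSet} (only lengths and names are used).
#' @param design numeric matrix of target depths, samples x contigs
#'   (dimnames required).
#' @param read_len read length in bp.
#' @param totals named numeric vector of per-sample total reads; defaults to
#'   10x the mapped count (at least 1e6).
#' @param seed integer seed.
#' @return a \code{\link{PlacementSet}}.
#' @export
simulatePlacements <- function(contigs, design, read_len = 100L, totals = NULL,
                               seed = 1L) {
  stopifnot(is.matrix(design), !is.null(rownames(design)),
            !is.null(colnames(design)), all(design >= 0))
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  used <- colnames(design)[colSums(design) > 0]
  if (any(read_len >= lens[used]))
    stop("read_len must be shorter than every targeted contig")
  withSeed(seed, {
    rows <- list()
    for (s in rownames(design)) for (cg in colnames(design)) {
      d <- design[s, cg]
      if (d <= 0) next
      L <- lens[[cg]]
      n <- rpois(1L, d * L / read_len)
      if (n == 0) next
      start0 <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, contig_id = cg, start = start0,
        end = start0 + read_len, stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), contig_id = character(),
                 start = integer(), end = integer())
    mapped <- table(factor(df$sample_id, levels = rownames(design)))
    if (is.null(totals))
      totals <- setNames(pmax(1e6, 10 * as.numeric(mapped)), rownames(design))
    if (any(totals[names(mapped)] < as.numeric(mapped)))
      stop("totals smaller than mapped read counts")
    gr <- GenomicRanges::GRanges(
      seqnames = df$contig_id,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      sample_id = df$sample_id,
      read_id = if (nrow(df)) sprintf("read%07d", seq_len(nrow(df))) else character())
    PlacementSet(gr, totals)
  })
}

#' Multi-sample community abundance design
#'
#' Log-normal feature abundances with multiplicative group effects on a
#' designated feature subset.  \code{effect_size = 1} gives an exchangeable
#' (null) design, useful for permutation-test calibration.
#'
#' @param n_samples_per_group samples per group.
#' @param groups character vector of group labels.
#' @param n_features number of features (>= 2).
#' @param effect_size multiplicative effect (> 0) applied to the affected
#'   subset in every group after the first.
#' @param dispersion log-scale sample-to-sample noise SD.
#' @param frac_affected fraction of features carrying the effect.
#' @param seed integer seed.
#' @return list: \code{abundance} (samples x features matrix, strictly
#'   positive), \code{groups} (factor), \code{affected} (feature indices).
#' @export
makeCommunityDesign <- function(n_samples_per_group, groups = c("P7", "P8"),
                                n_features = 50L, effect_size = 1,
                                dispersion = 0.5, frac_affected = 0.3,
                                seed = 1L) {
  stopifnot(n_samples_per_group >= 1, length(groups) >= 1, n_features >= 2,
            effect_size > 0, dispersion > 0)
  withSeed(seed, {
    g <- factor(rep(groups, each = n_samples_per_group), levels = groups)
    n <- length(g)
    baseline <- exp(rnorm(n_features, mean = log(10), sd = 1))
    affected <- seq_len(max(1L, round(frac_affected * n_features)))
    eff <- matrix(1, n, n_features)
    if (length(groups) > 1)
      eff[as.integer(g) > 1L, affected] <- effect_size
    ab <- matrix(baseline, n, n_features, byrow = TRUE) * eff *
      exp(matrix(rnorm(n * n_features, 0, dispersion), n, n_features))
    dimnames(ab) <- list(sprintf("%s_s%02d", g, seq_len(n)),
                         sprintf("feat%03d", seq_len(n_features)))
    list(abundance = ab, groups = g, affected = affected)
  })
}

## Host-specific codon (triplet) usage: a Dirichlet draw over the 64
## triplets whose marginal base composition is tilted toward the target
## GC.  Sequences built from such triplets carry phase-dependent k-mer
## structure beyond any low-order Markov background -- the same signal
## (codon bias shared between a virus and its host) that alignment-free
## host prediction exploits in real genomes.
randomCodonUsage <- function(gc, concentration = 0.5) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  trip <- expand.grid(b1 = DNA_BASES, b2 = DNA_BASES, b3 = DNA_BASES,
                      stringsAsFactors = FALSE)
  codons <- paste0(trip$b1, trip$b2, trip$b3)
  mean_p <- base_p[trip$b1] * base_p[trip$b2] * base_p[trip$b3]
  w <- rgamma(64, shape = concentration * 64 * mean_p)
  setNames(w / sum(w), codons)
}

## sequence of length_bp built by concatenating iid triplets drawn from a
## codon-usage distribution
codonGenome <- function(length_bp, codon_probs, seed = 1L, id = "seq1",
                        role = "host") {
  seq <- withSeed(seed, {
    n3 <- ceiling(length_bp / 3)
    substr(paste(sample(names(codon_probs), n3, replace = TRUE,
                        prob = codon_probs), collapse = ""), 1L, length_bp)
  })
  asRecord(seq, id, role = role)
}

## Random taxonomy lineages: a small synthetic pool with shared upper ranks
## so LCA aggregation has non-trivial cases.
randomLineages <- function(n) {
  phyla <- c("Proteobacteria", "Chloroflexi", "Nitrospirae", "Firmicutes",
             "Halobacterota")
  doms <- c(rep("Bacteria", 4), "Archaea")
  idx <- sample(length(phyla), n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    p <- idx[i]
    paste(doms[p], phyla[p],
          paste0("Class", p, "_", sample(2, 1)),
          paste0("Order", p, "_", sample(2, 1)),
          paste0("Family", p, "_", sample(3, 1)),
          paste0("Genus", p, "_", sample(4, 1)),
          paste0("sp", sample(99, 1)), sep = ";")
  }, character(1))
}

#' Generate a full synthetic sediment community with ground truth
#'
#' Emulates the study design the pipeline targets: two wetlands x three
#' depths (x seasons collapsed into replicate samples), compositionally
#' distinct host genomes (GC 0.30-0.70), viral contig families of known
#' membership (intra-family divergence <= 2\%, between-family up to ~15\%),
#' implanted prophages and CRISPR arrays, read placements tracking a
#' designed abundance matrix, a marker-gene hit table (dsrA/dsrD/mcrA) and a
#' geochemistry matrix with a wetland effect.
#'
#' @param n_hosts number of host genomes.
#' @param host_len host genome length (bp).
#' @param n_families number of viral contig families.
#' @param n_viruses total number of clustering-eligible viral contigs.
#' @param n_short additional short (< 5 kb) viral contigs, excluded from
#'   clustering.
#' @param n_prophages prophages to implant (one per host, first hosts).
#' @param n_crispr hosts receiving a CRISPR array.
#' @param spacers_per_array spacers per CRISPR array.
#' @param n_samples_per_group samples per wetland.
#' @param read_len read length for placement simulation.
#' @param seed integer seed.
#' @return a list with elements \code{hosts}, \code{viruses} (both
#'   \code{DNAStringSet} with metadata), \code{truth} (prophage_links,
#'   crispr_links, votu_membership, group_design), \code{placements}
#'   (a \code{PlacementSet}), \code{design} (true depth matrix),
#'   \code{sample_meta}, \code{marker_hits} and \code{geochem}.
#' @export
makeCommunity <- function(n_hosts = 20L, host_len = 60000L, n_families = 12L,
                          n_viruses = 50L, n_short = 10L, n_prophages = 10L,
                          n_crispr = 3L, spacers_per_array = 4L,
                          n_samples_per_group = 6L, read_len = 100L,
                          seed = 1L) {
  withSeed(seed, {
    ## --- hosts: each genome gets its own codon-usage distribution on a
    ## distinct GC backbone (0.30-0.70, realistic for sediment microbes);
    ## the triplet phase structure is what composition-based host
    ## prediction exploits in real genomes
    host_gc <- runif(n_hosts, 0.30, 0.70)
    host_codons <- lapply(host_gc, randomCodonUsage)
    hosts <- do.call(c, lapply(seq_len(n_hosts), function(i)
      codonGenome(host_len, host_codons[[i]], seed = sample.int(1e6, 1),
                  id = sprintf("host%02d", i), role = "host")))
    S4Vectors::mcols(hosts)$taxonomy <- randomLineages(n_hosts)
    S4Vectors::mcols(hosts)$gc <- host_gc

    ## --- viral families: parents adopt a host's composition (so the
    ## composition-based linkage methods have signal); members are lightly
    ## mutated copies; some parents are 10-15%-diverged copies of another
    ## parent, spanning divergence up to ~15% without blurring family truth
    fam_host <- sample(n_hosts, n_families, replace = TRUE)
    fam_len <- sample(5500:15000, n_families, replace = TRUE)
    parents <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      if (f > 2 && runif(1) < 0.25) {
        src <- sample(f - 1L, 1L)
        parents[[f]] <- mutateSequence(parents[[src]],
                                       sub_rate = runif(1, 0.10, 0.15),
                                       seed = sample.int(1e6, 1),
                                       id = sprintf("vfam%02d_parent", f))
        fam_host[f] <- fam_host[src]
      } else {
        parents[[f]] <- codonGenome(fam_len[f], host_codons[[fam_host[f]]],
                                    seed = sample.int(1e6, 1),
                                    id = sprintf("vfam%02d_parent", f),
                                    role = "viral")
      }
    }
    sizes <- rep(1L, n_families)
    extra <- n_viruses - n_families
    if (extra > 0) {
      add <- table(factor(sample(n_families, extra, replace = TRUE),
                          levels = seq_len(n_families)))
      sizes <- sizes + as.integer(add)
    }
    vir_list <- list(); membership <- character(); vhost <- integer()
    for (f in seq_len(n_families)) {
      for (j in seq_len(sizes[f])) {
        vid <- sprintf("virus_f%02d_m%02d", f, j)
        rec <- if (j == 1L)
          asRecord(asSequenceChar(parents[[f]]), vid, role = "viral")
        else
          mutateSequence(parents[[f]], sub_rate = runif(1, 0, 0.02),
                         seed = sample.int(1e6, 1), id = vid)
        vir_list[[vid]] <- rec
        membership[vid] <- sprintf("fam%02d", f)
        vhost[vid] <- fam_host[f]
      }
    }
    ## short contigs (>= 1.5 kb, <= 5 kb): real pools carry many of these
    for (j in seq_len(n_short)) {
      vid <- sprintf("virus_short%02d", j)
      vir_list[[vid]] <- makeGenome(sample(1500:5000, 1),
                                    gc = runif(1, 0.35, 0.65),
                                    markov_order = 0L, seed = sample.int(1e6, 1),
                                    id = vid, role = "viral")
      membership[vid] <- sprintf("short%02d", j)
      vhost[vid] <- NA_integer_
    }
    viruses <- do.call(c, unname(vir_list))

    ## --- prophages: implant family parents into their composition host.
    ## Positions are drawn on the original host coordinates and applied in
    ## descending order per host, so no implant can land inside (and
    ## split) an earlier one.
    prophage_truth <- NULL
    pro_virus <- names(viruses)[match(
      sprintf("fam%02d", seq_len(n_families)), membership)]
    pro_pick <- seq_len(min(n_prophages, n_families))
    impl <- data.frame(virus = pro_virus[pro_pick], hid = fam_host[pro_pick])
    impl$pos <- NA_integer_
    for (h in unique(impl$hid)) {
      idx <- which(impl$hid == h)
      impl$pos[idx] <- sort(sample.int(Biostrings::width(hosts)[h] - 1L,
                                       length(idx)), decreasing = TRUE)
    }
    for (i in seq_len(nrow(impl))) {
      res <- implantProphage(hosts[impl$hid[i]], viruses[impl$virus[i]],
                             impl$pos[i])
      hosts[impl$hid[i]] <- res$host
      prophage_truth <- rbind(prophage_truth, res$truth)
    }

    ## --- CRISPR arrays
    crispr_truth <- NULL
    crispr_hosts <- sample(setdiff(seq_len(n_hosts), unique(fam_host[pro_pick])),
                           n_crispr)
    eligible <- viruses[Biostrings::width(viruses) >= 50]
    for (hid in crispr_hosts) {
      pos <- sample.int(Biostrings::width(hosts)[hid] - 1L, 1L)
      res <- implantCrisprArray(hosts[hid],
                                eligible[sample(length(eligible),
                                                spacers_per_array)],
                                n_spacers = spacers_per_array,
                                repeat_len = sample(24:36, 1),
                                spacer_len = sample(28:36, 1),
                                position = pos, seed = sample.int(1e6, 1))
      hosts[hid] <- res$host
      crispr_truth <- rbind(crispr_truth, res$truth)
    }

    ## --- sample design and placements (wetland x depth, depth-decaying
    ## abundance with a wetland effect on a subset of contigs)
    wet <- c("P7", "P8"); dep <- c("shallow", "mid", "deep")
    n_samp <- 2L * n_samples_per_group
    meta <- data.frame(
      sample_id = sprintf("%s_%s_%d", rep(wet, each = n_samples_per_group),
                          rep(dep, length.out = n_samples_per_group),
                          rep(seq_len(n_samples_per_group), 2)),
      wetland = rep(wet, each = n_samples_per_group),
      depth = rep(rep(dep, length.out = n_samples_per_group), 2),
      season = sample(c("winter", "spring", "summer"), n_samp, replace = TRUE),
      stringsAsFactors = FALSE)
    all_contigs <- c(hosts, viruses)
    nC <- length(all_contigs)
    base_depth <- exp(rnorm(nC, log(8), 0.8))
    wet_eff <- ifelse(runif(nC) < 0.4, 4, 1)   # P7-enriched subset
    dep_fac <- c(shallow = 1.4, mid = 1.0, deep = 0.6)
    design <- matrix(0, n_samp, nC,
                     dimnames = list(meta$sample_id, names(all_contigs)))
    for (i in seq_len(n_samp)) {
      e <- if (meta$wetland[i] == "P7") wet_eff else 1 / wet_eff
      design[i, ] <- base_depth * e * dep_fac[[meta$depth[i]]] *
        exp(rnorm(nC, 0, 0.3))
    }
    ## sparsity: drop ~25% of (sample, virus) cells to zero
    vmask <- matrix(runif(n_samp * nC) < 0.25, n_samp, nC)
    vmask[, seq_len(n_hosts)] <- FALSE
    design[vmask] <- 0
    placements <- simulatePlacements(all_contigs, design, read_len = read_len,
                                     seed = sample.int(1e6, 1))

    ## --- marker-gene hits on host contigs (guild assignment by phylum)
    phylum <- vapply(strsplit(S4Vectors::mcols(hosts)$taxonomy, ";"),
                     `[`, character(1), 2)
    marker <- ifelse(phylum == "Halobacterota", "mcrA",
                     ifelse(seq_len(n_hosts) %% 2 == 0, "dsrA", "dsrD"))
    marker_hits <- data.frame(
      gene_id = sprintf("%s_gene%02d", names(hosts), seq_len(n_hosts)),
      contig_id = names(hosts),
      marker = marker,
      protein_len = ifelse(marker == "dsrA", sample(250:450, n_hosts, TRUE),
                    ifelse(marker == "dsrD", sample(40:90, n_hosts, TRUE),
                           sample(100:600, n_hosts, TRUE))),
      taxon = S4Vectors::mcols(hosts)$taxonomy,
      direction = ifelse(marker == "dsrA",
                         sample(c("reductive", "oxidative"), n_hosts, TRUE,
                                prob = c(0.8, 0.2)), "unknown"),
      stringsAsFactors = FALSE)

    ## --- gene annotations on viral contigs (for the AMG screen): most
    ## contigs carry hallmark genes; one allow-listed metabolic product
    ## (cysH) is planted at interior positions on >= 3 contigs, plus
    ## negative controls (edge position, rare product)
    vids <- names(viruses)
    ann <- list()
    amg_contigs <- vids[seq_len(min(4L, length(vids)))]
    rare_contigs <- vids[5:6]
    for (vid in vids) {
      ng <- max(8L, as.integer(Biostrings::width(viruses[vid]) / 1500))
      prod <- rep("hypothetical protein", ng)
      cat_ <- rep("other", ng)
      hall <- sample(ng, 2L)
      prod[hall] <- c("capsid protein", "tail protein")[seq_along(hall)]
      cat_[hall] <- "viral_hallmark"
      if (vid %in% amg_contigs) {
        at <- sample(3:(ng - 2L), 1L)   # interior (0-based index at-1)
        prod[at] <- "cysH"; cat_[at] <- "metabolic"
      }
      if (vid %in% rare_contigs) {
        at <- sample(3:(ng - 2L), 1L)
        prod[at] <- "psbA"; cat_[at] <- "metabolic"
      }
      ann[[vid]] <- data.frame(
        contig_id = vid, gene_id = sprintf("%s_g%03d", vid, seq_len(ng)),
        gene_index = seq_len(ng) - 1L, n_genes_on_contig = ng,
        product = prod, category = cat_, stringsAsFactors = FALSE)
    }
    gene_annotations <- do.call(rbind, ann)
    rownames(gene_annotations) <- NULL

    ## --- geochemistry with a wetland effect (pore-water analytes)
    vars <- c("sulfate", "sulfide", "iron_II", "methane", "methanol",
              "ethanol", "propanol_2", "acetate")
    gmu <- exp(rnorm(length(vars), log(50), 0.5))
    geff <- c(2.5, 0.4, 1.5, 0.5, 1.8, 2.2, 2.0, 0.7)
    geo <- t(vapply(seq_len(n_samp), function(i) {
      e <- if (meta$wetland[i] == "P7") geff else 1 / geff
      gmu * e * exp(rnorm(length(vars), 0, 0.25))
    }, numeric(length(vars))))
    dimnames(geo) <- list(meta$sample_id, vars)

    list(hosts = hosts, viruses = viruses,
         truth = list(prophage_links = prophage_truth,
                      crispr_links = crispr_truth,
                      votu_membership = membership,
                      virus_host = setNames(
                        ifelse(is.na(vhost), NA, sprintf("host%02d", vhost)),
                        names(membership)),
                      group_design = meta),
         placements = placements, design = design, sample_meta = meta,
         marker_hits = marker_hits, gene_annotations = gene_annotations,
         amg_truth = "cysH", geochem = geo)
  })
}

#' Write a synthetic community to disk
#'
#' Emits FASTA for hosts and viruses, TSV for placements, totals, design,
#' truth tables, sample metadata and geochemistry, plus a manifest with MD5
#' checksums, all under one directory.
#'
#' @param community result of \code{\link{makeCommunity}}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeCommunity <- function(community, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  Biostrings::writeXStringSet(community$hosts, fp("hosts.fasta"))
  Biostrings::writeXStringSet(community$viruses, fp("viruses.fasta"))
  writePlacementsTSV(community$placements, fp("placements.tsv"),
                     fp("totals.tsv"))
  wt <- function(d, f) write.table(d, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(community$truth$prophage_links, "truth_prophages.tsv")
  wt(community$truth$crispr_links, "truth_crispr.tsv")
  wt(data.frame(contig_id = names(community$truth$votu_membership),
                family = unname(community$truth$votu_membership)),
     "truth_votus.tsv")
  wt(community$sample_meta, "samples.tsv")
  write.table(community$geochem, fp("geochem.tsv"), sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(community$design, fp("true_depth.tsv"), sep = "\t", quote = FALSE,
              col.names = NA)
  wt(community$marker_hits, "marker_hits.tsv")
  wt(community$gene_annotations, "gene_annotations.tsv")
  tax <- data.frame(host_id = names(community$hosts),
                    taxonomy = S4Vectors::mcols(community$hosts)$taxonomy)
  wt(tax, "host_taxonomy.tsv")
  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files), md5 = tools::md5sum(files),
                         row.names = NULL)
  wt(manifest, "MANIFEST.tsv")
  invisible(manifest)
}
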