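#' @importFrom stats runif rnbinom rpois rlnorm rmultinom
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' statistical structure the analysis assumes: multi-exon transcript
#' models on multiple scaffolds, coding genes with planted in-frame ORFs
#' of at least 100 aa, lncRNAs whose every reading frame is broken by stop
#' codons (longest ORF well below 100 aa by construction), planted
#' positional classes (intergenic/antisense/intronic/other), one decoy
#' class per identification filter, negative-binomial counts across six
#' tissues with planted tissue-specific transcripts and co-expressed
#' blocks, and planted enriched annotation terms.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param nScaffolds,scaffoldLength genome shape (default 6 scaffolds of
#'   600 kb).
#' @param nCoding number of coding genes (one transcript each).
#' @param nLncIntergenic,nLncAntisense,nLncIntronic,nLncOther planted
#'   positional-class counts (defaults 70/19/5/6, the composition reported
#'   for plant lncRNA sets of this kind).
#' @param nDecoyShort,nDecoySingleExon,nDecoyNoStrand,nDecoyLongOrf,nDecoyLowSupport
#'   decoys violating exactly one identification filter each (default 5
#'   each).
#' @param tissues tissue names (default the six rubber-tree tissues:
#'   root, bark, leaf, latex, flower, seed).
#' @param replicates replicates per tissue (default 3).
#' @param dispersion negative-binomial dispersion (default 0.04, a
#'   biological coefficient of variation of 0.2 — the standard figure for
#'   replicate libraries of near-isogenic material such as a clonal
#'   cultivar; 0 gives Poisson counts).
#' @param baselineMean baseline per-sample mean count for a 1 kb coding
#'   transcript (default 200, emulating deep libraries).
#' @param lncExprRatio expression of lncRNAs relative to mRNAs
#'   (default 0.25 — lncRNAs are lowly expressed).
#' @param specificityFold mean multiplier in a specific transcript's
#'   target tissue (default 25, giving an expected max fraction
#'   25/(25+5) ~ 0.83 > 0.6).
#' @param propSpecificLnc,propSpecificMrna fraction of lncRNAs/mRNAs given
#'   a planted specific tissue (defaults 0.4 and 0.1 — lncRNAs are more
#'   tissue-specific).
#' @param nBlocks,blockCoding,blockLnc,blockSd co-expression blocks:
#'   number, coding and lncRNA members per block, and the log-normal
#'   sdlog of the shared per-sample latent factor (default 3 blocks of
#'   8 + 2, sdlog 2). The factor is rebalanced to mean 1 within every
#'   tissue's replicates, keeping block co-expression orthogonal to the
#'   planted tissue specificity.
#' @param libSizeRange fold range of library-size factors, drawn
#'   log-uniform (default 4, so TMM has work to do).
#' @param nTermsBP,nTermsKEGG,termsPerGene background annotation sizes.
#' @param plantedFraction fraction of a block's coding members annotated
#'   with its planted term (default 1).
#' @param backgroundTermRate probability a non-member gene carries a
#'   planted term (default 0.02).
#' @param gcCoding,gcLnc,gcBackground nucleotide composition knobs
#'   (lncRNAs are AT-richer than mRNAs).
#' @return a validated list of class `lncSimConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nScaffolds = 6L, scaffoldLength = 600000L,
                             nCoding = 100L,
                             nLncIntergenic = 70L, nLncAntisense = 19L,
                             nLncIntronic = 5L, nLncOther = 6L,
                             nDecoyShort = 5L, nDecoySingleExon = 5L,
                             nDecoyNoStrand = 5L, nDecoyLongOrf = 5L,
                             nDecoyLowSupport = 5L,
                             tissues = c("root", "bark", "leaf", "latex",
                                         "flower", "seed"),
                             replicates = 3L,
                             dispersion = 0.04, baselineMean = 200,
                             lncExprRatio = 0.25, specificityFold = 25,
                             propSpecificLnc = 0.4, propSpecificMrna = 0.1,
                             nBlocks = 3L, blockCoding = 8L, blockLnc = 2L,
                             blockSd = 2,
                             libSizeRange = 4,
                             nTermsBP = 30L, nTermsKEGG = 20L,
                             termsPerGene = 3L, plantedFraction = 1,
                             backgroundTermRate = 0.02,
                             gcCoding = 0.45, gcLnc = 0.33,
                             gcBackground = 0.36) {
  cfg <- as.list(environment())
  counts <- c(cfg$nCoding, cfg$nLncIntergenic, cfg$nLncAntisense,
              cfg$nLncIntronic, cfg$nLncOther, cfg$nDecoyShort,
              cfg$nDecoySingleExon, cfg$nDecoyNoStrand, cfg$nDecoyLongOrf,
              cfg$nDecoyLowSupport)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (length(cfg$tissues) < 2L) stop("need >= 2 tissues")
  if (cfg$specificityFold < 1) stop("specificityFold must be >= 1")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$replicates < 1L) stop("need >= 1 replicate per tissue")
  nHosts <- cfg$nLncAntisense + cfg$nLncIntronic + cfg$nLncOther
  if (nHosts > cfg$nCoding) stop("not enough coding genes to host planted classes")
  class(cfg) <- "lncSimConfig"
  cfg
}

STOP_TRIPLE <- "TTAATTAATTAA"  # a stop codon in each of the three frames

randomBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# random DNA whose every reading frame hits a stop at least every 45 nt,
# so no ORF can approach 100 aa regardless of chance ATGs
frameBrokenDNA <- function(len, gc) {
  nUnit <- ceiling(len / 45) + 1L
  units <- vapply(seq_len(nUnit), function(i) {
    paste0(paste(randomBases(33L, gc), collapse = ""), STOP_TRIPLE)
  }, "")
  substr(paste(units, collapse = ""), 1L, len)
}

# coding-style RNA: UTR + ATG + (aa - 1) sense codons + stop + UTR;
# longest ORF is >= aa by construction
codingRNA <- function(aa, utr5, utr3, gc) {
  codons <- apply(matrix(randomBases(3L * (aa - 1L), gc), nrow = 3L), 2,
                  paste, collapse = "")
  codons[codons %in% c("TAA", "TAG", "TGA")] <- "GAT"
  paste0(frameBrokenDNA(utr5, gc), "ATG", paste(codons, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L), frameBrokenDNA(utr3, gc))
}

# split total into k integer parts, each >= minPart
splitLengths <- function(total, k, minPart) {
  if (k == 1L) return(total)
  stopifnot(total >= k * minPart)
  extra <- total - k * minPart
  cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, extra))
  as.integer(minPart + parts)
}

# place an RNA sequence onto genomic exons (ascending); minus-strand
# transcripts store the reverse complement so that splicing recovers rna
orientedExonPieces <- function(rna, widths, strand) {
  s <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(rna)))
  } else rna
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  substring(s, starts, ends)
}

#' Simulate a genome with planted transcript classes
#'
#' Generates scaffold sequences, a transcript annotation, and a truth
#' table. Coding genes carry planted in-frame ORFs (>= 100 aa); all
#' planted lncRNAs are frame-broken (stop codons in every frame at least
#' every 45 nt) so their longest ORF stays far below 100 aa — verified at
#' generation. Positional classes are planted geometrically: intergenic
#' lncRNAs sit in gaps clear of every gene span; antisense lncRNAs share
#' 150 bp of exon with an opposite-strand coding gene; intronic lncRNAs
#' sit wholly inside one intron of a same-strand gene; "other" lncRNAs sit
#' inside an intron of an opposite-strand gene. Each decoy class violates
#' exactly one identification filter. Deterministic under the config seed.
#' In the annotation, coding transcripts carry `biotype = "coding"` and
#' everything else `"candidate"` — truth labels are never leaked to the
#' pipeline.
#'
#' @param config an `lncSimConfig` from [simulationConfig()].
#' @return a list: `seqs` (`DNAStringSet`), `annotation`
#'   ([TranscriptSet-class]), `truth` (data.frame `transcript_id`,
#'   `gene_id`, `true_class`, `host_gene`, `true_specific_tissue`,
#'   `coexpression_block`, `planted_term_bp`, `planted_term_kegg`).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "lncSimConfig"))
  set.seed(config$seed)
  nHosts <- config$nLncAntisense + config$nLncIntronic + config$nLncOther

  genes <- vector("list", config$nCoding)
  scafOf <- rep_len(seq_len(config$nScaffolds), config$nCoding)
  cursor <- rep(1500L, config$nScaffolds)
  gaps <- list()   # free intergenic intervals, one after each gene
  for (i in seq_len(max(config$nCoding, 1L)) ) {
    if (config$nCoding == 0L) break
    sc <- scafOf[i]
    strand <- if (i %% 2L == 1L) "+" else "-"
    aa <- sample(110:300, 1L)
    utr5 <- sample(60:150, 1L)
    utr3 <- sample(80:250, 1L)
    rna <- codingRNA(aa, utr5, utr3, config$gcCoding)
    mlen <- nchar(rna)
    k <- sample(4:8, 1L)
    isHost <- i <= nHosts
    if (isHost) {
      w1 <- sample(200:280, 1L)
      k <- max(2L, min(k, 1L + (mlen - w1) %/% 60L))
      widths <- c(w1, splitLengths(mlen - w1, k - 1L, 60L))
    } else {
      k <- max(2L, min(k, mlen %/% 60L))
      widths <- splitLengths(mlen, k, 60L)
    }
    introns <- sample(120:700, k - 1L, replace = TRUE)
    if (isHost) introns[1] <- sample(2400:3000, 1L)
    span <- sum(widths) + sum(introns)
    gstart <- cursor[sc]
    if (gstart + span + 8500L > config$scaffoldLength) {
      stop("scaffold too short for requested gene count")
    }
    exStarts <- gstart + cumsum(c(0L, widths[-k] + introns))
    exEnds <- exStarts + widths - 1L
    gap <- sample(4800:7000, 1L)
    cursor[sc] <- exEnds[k] + gap + 1L
    genes[[i]] <- list(id = i, scaffold = sc, strand = strand,
                       starts = exStarts, ends = exEnds, rna = rna,
                       aa = aa, intron1 = if (k > 1L) c(exEnds[1] + 1L, exStarts[2] - 1L) else NULL)
    gaps[[i]] <- list(scaffold = sc, lo = exEnds[k] + 1L, hi = exEnds[k] + gap)
  }

  nGapPlaced <- config$nLncIntergenic + config$nDecoyShort +
    config$nDecoySingleExon + config$nDecoyNoStrand +
    config$nDecoyLongOrf + config$nDecoyLowSupport
  if (nGapPlaced > length(gaps)) {
    stop("not enough intergenic gaps: increase nCoding or reduce gap-placed classes")
  }

  others <- list()  # non-coding transcript plans
  gapIdx <- 0L
  placeInGap <- function(widths, introns) {
    gapIdx <<- gapIdx + 1L
    g <- gaps[[gapIdx]]
    span <- sum(widths) + sum(introns)
    stopifnot(g$lo + 600L + span - 1L <= g$hi - 600L)
    k <- length(widths)
    starts <- g$lo + 600L + cumsum(c(0L, widths[-k] + introns))
    list(scaffold = g$scaffold, starts = starts, ends = starts + widths - 1L)
  }
  addPlan <- function(class, prefix, idx, widths, introns, strand, rna,
                      host = NA_integer_, starts = NULL, ends = NULL,
                      inherited = 0L) {
    if (is.null(starts)) {
      pos <- placeInGap(widths, introns)
      starts <- pos$starts; ends <- pos$ends
      scaffold <- pos$scaffold
    } else {
      scaffold <- genes[[host]]$scaffold
    }
    others[[length(others) + 1L]] <<- list(
      id = sprintf("%s.%03d", prefix, idx), class = class,
      scaffold = scaffold, strand = strand, starts = starts, ends = ends,
      rna = rna, host = host, inherited = inherited)
  }

  for (j in seq_len(config$nLncIntergenic)) {
    len <- sample(280:800, 1L)
    k <- sample(2:3, 1L)
    widths <- splitLengths(len, k, 80L)
    introns <- sample(100:350, k - 1L, replace = TRUE)
    addPlan("lncRNA_intergenic", "lnc.inter", j, widths, introns,
            sample(c("+", "-"), 1L), frameBrokenDNA(len, config$gcLnc))
  }
  hostAt <- 0L
  for (j in seq_len(config$nLncAntisense)) {
    hostAt <- hostAt + 1L
    g <- genes[[hostAt]]
    lenB <- sample(150:320, 1L)
    exA <- c(g$ends[1] - 149L, g$ends[1])
    exB <- c(g$ends[1] + 300L, g$ends[1] + 300L + lenB - 1L)
    strand <- if (g$strand == "+") "-" else "+"
    addPlan("lncRNA_antisense", "lnc.anti", j, NULL, NULL, strand,
            frameBrokenDNA(lenB, config$gcLnc), host = hostAt,
            starts = c(exA[1], exB[1]), ends = c(exA[2], exB[2]),
            inherited = 1L)
  }
  intronPlan <- function(class, prefix, j, sameStrand) {
    hostAt <<- hostAt + 1L
    g <- genes[[hostAt]]
    iS <- g$intron1[1]
    w1 <- sample(130:260, 1L); gp <- sample(90:160, 1L)
    w2 <- sample(130:260, 1L)
    s1 <- iS + 120L
    starts <- c(s1, s1 + w1 + gp)
    ends <- starts + c(w1, w2) - 1L
    strand <- if (sameStrand) g$strand else if (g$strand == "+") "-" else "+"
    addPlan(class, prefix, j, NULL, NULL, strand,
            frameBrokenDNA(w1 + w2, config$gcLnc), host = hostAt,
            starts = starts, ends = ends)
  }
  for (j in seq_len(config$nLncIntronic)) {
    intronPlan("lncRNA_intronic", "lnc.intr", j, sameStrand = TRUE)
  }
  for (j in seq_len(config$nLncOther)) {
    intronPlan("lncRNA_other", "lnc.other", j, sameStrand = FALSE)
  }
  for (j in seq_len(config$nDecoyShort)) {
    len <- sample(120:180, 1L)
    widths <- splitLengths(len, 2L, 50L)
    addPlan("decoy_short", "decoy.short", j, widths, sample(80:200, 1L),
            sample(c("+", "-"), 1L), frameBrokenDNA(len, config$gcLnc))
  }
  for (j in seq_len(config$nDecoySingleExon)) {
    len <- sample(300:700, 1L)
    addPlan("decoy_single_exon", "decoy.single", j, len, integer(0),
            sample(c("+", "-"), 1L), frameBrokenDNA(len, config$gcLnc))
  }
  for (j in seq_len(config$nDecoyNoStrand)) {
    len <- sample(300:600, 1L)
    widths <- splitLengths(len, 2L, 80L)
    addPlan("decoy_no_strand", "decoy.nostrand", j, widths,
            sample(100:300, 1L), "*", frameBrokenDNA(len, config$gcLnc))
  }
  for (j in seq_len(config$nDecoyLongOrf)) {
    aa <- sample(120:200, 1L)
    rna <- codingRNA(aa, 30L, 30L, config$gcCoding)
    widths <- splitLengths(nchar(rna), 2L, 80L)
    addPlan("decoy_long_orf", "decoy.longorf", j, widths,
            sample(100:300, 1L), sample(c("+", "-"), 1L), rna)
  }
  for (j in seq_len(config$nDecoyLowSupport)) {
    len <- sample(300:600, 1L)
    widths <- splitLengths(len, 2L, 80L)
    addPlan("decoy_low_support", "decoy.lowsupp", j, widths,
            sample(100:300, 1L), sample(c("+", "-"), 1L),
            frameBrokenDNA(len, config$gcLnc))
  }

  # assemble scaffold sequences: random background, then planted segments
  scafNames <- sprintf("scaffold_%02d", seq_len(config$nScaffolds))
  chars <- lapply(seq_len(config$nScaffolds), function(s) {
    randomBases(config$scaffoldLength, config$gcBackground)
  })
  writeSegs <- function(sc, starts, ends, pieces) {
    for (q in seq_along(starts)) {
      chars[[sc]][starts[q]:ends[q]] <<-
        strsplit(pieces[q], "")[[1]]
    }
  }
  for (g in genes) {
    if (is.null(g)) next
    pieces <- orientedExonPieces(g$rna, g$ends - g$starts + 1L, g$strand)
    writeSegs(g$scaffold, g$starts, g$ends, pieces)
  }
  for (o in others) {
    widths <- o$ends - o$starts + 1L
    strandForContent <- if (o$strand == "*") "+" else o$strand
    if (o$inherited > 0L) {
      # leading exon(s) inherit host-gene content already on the genome;
      # only the free exons carry the constructed frame-broken sequence
      free <- seq_along(widths)[-seq_len(o$inherited)]
      pieces <- orientedExonPieces(o$rna, widths[free], strandForContent)
      writeSegs(o$scaffold, o$starts[free], o$ends[free], pieces)
    } else {
      pieces <- orientedExonPieces(o$rna, widths, strandForContent)
      writeSegs(o$scaffold, o$starts, o$ends, pieces)
    }
  }
  seqs <- Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
  names(seqs) <- scafNames

  # annotation
  mkGr <- function(sc, starts, ends, strand) {
    GenomicRanges::GRanges(scafNames[sc],
                           IRanges::IRanges(starts, ends), strand = strand)
  }
  exList <- list(); gid <- character(); bio <- character()
  truth <- list()
  for (g in genes) {
    if (is.null(g)) next
    tid <- sprintf("mrna.%04d", g$id)
    exList[[tid]] <- mkGr(g$scaffold, g$starts, g$ends, g$strand)
    gid <- c(gid, sprintf("gene.%04d", g$id))
    bio <- c(bio, "coding")
    truth[[length(truth) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = sprintf("gene.%04d", g$id),
      true_class = "coding", host_gene = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (o in others) {
    exList[[o$id]] <- mkGr(o$scaffold, o$starts, o$ends, o$strand)
    gid <- c(gid, paste0("g.", o$id))
    bio <- c(bio, "candidate")
    truth[[length(truth) + 1L]] <- data.frame(
      transcript_id = o$id, gene_id = paste0("g.", o$id),
      true_class = o$class,
      host_gene = if (is.na(o$host)) NA_character_ else sprintf("gene.%04d", o$host),
      stringsAsFactors = FALSE)
  }
  grl <- GRangesList(exList)
  annotation <- TranscriptSet(grl, geneId = gid, biotype = bio)
  truth <- do.call(rbind, truth)

  # planted specificity and co-expression blocks
  truth$true_specific_tissue <- NA_character_
  truth$coexpression_block <- NA_integer_
  truth$planted_term_bp <- NA_character_
  truth$planted_term_kegg <- NA_character_
  isLnc <- startsWith(truth$true_class, "lncRNA_")
  isCod <- truth$true_class == "coding"
  nSpecL <- round(config$propSpecificLnc * sum(isLnc))
  nSpecM <- round(config$propSpecificMrna * sum(isCod))
  specL <- sample(which(isLnc), nSpecL)
  specM <- sample(which(isCod), nSpecM)
  truth$true_specific_tissue[c(specL, specM)] <-
    sample(config$tissues, nSpecL + nSpecM, replace = TRUE)
  freeC <- which(isCod & is.na(truth$true_specific_tissue))
  freeL <- which(isLnc & is.na(truth$true_specific_tissue))
  needC <- config$nBlocks * config$blockCoding
  needL <- config$nBlocks * config$blockLnc
  if (length(freeC) < needC || length(freeL) < needL) {
    stop("not enough non-specific transcripts for the requested blocks")
  }
  pickC <- sample(freeC, needC)
  pickL <- sample(freeL, needL)
  for (b in seq_len(config$nBlocks)) {
    mem <- c(pickC[((b - 1L) * config$blockCoding + 1L):(b * config$blockCoding)],
             pickL[((b - 1L) * config$blockLnc + 1L):(b * config$blockLnc)])
    truth$coexpression_block[mem] <- b
    truth$planted_term_bp[mem] <- sprintf("GO:PLANT%02d", b)
    truth$planted_term_kegg[mem] <- sprintf("koPLANT%02d", b)
  }

  # generation-time verification of the planted coding structure
  sp <- spliceTranscriptSeq(
    annotation[txStrand(annotation) != "*"], seqs)
  orf <- vapply(as.character(sp), longestOrf, integer(1))
  codIds <- truth$transcript_id[isCod]
  if (any(orf[codIds] < 100L)) stop("internal: planted coding ORF lost")
  lncIds <- intersect(truth$transcript_id[isLnc | truth$true_class %in%
    c("decoy_short", "decoy_low_support")], names(orf))
  if (any(orf[lncIds] >= 100L)) stop("internal: planted lncRNA gained an ORF")

  list(seqs = seqs, annotation = annotation, truth = truth)
}

#' Simulate negative-binomial counts with planted structure
#'
#' Per-transcript, per-sample mean = `baselineMean x biotype ratio x
#' (length / 1 kb) x tissue multiplier x block latent factor x library
#' factor`, with the tissue multiplier equal to `specificityFold` in the
#' transcript's planted tissue and 1 elsewhere, the latent factor shared
#' by all members of a co-expression block (log-normal per sample, mean
#' 1), and library factors log-uniform over a `libSizeRange`-fold range.
#' Counts are negative binomial with the configured dispersion (Poisson
#' at dispersion 0). Low-support decoys get a planted total of at most 5
#' reads. Deterministic under `seed`.
#'
#' @param truth truth table from [simulateGenome()].
#' @param lengths named spliced lengths (`txLengths()` of the annotation).
#' @param config an `lncSimConfig`.
#' @param seed count-level seed (default `config$seed + 1`).
#' @return a list: `counts` (integer matrix transcripts x samples),
#'   `design` (data.frame `sample_id`, `tissue`).
#' @export
simulateCounts <- function(truth, lengths, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "lncSimConfig"))
  set.seed(seed)
  tissues <- config$tissues
  design <- data.frame(
    sample_id = paste0(rep(tissues, each = config$replicates), "_",
                       seq_len(config$replicates)),
    tissue = rep(tissues, each = config$replicates),
    stringsAsFactors = FALSE)
  nS <- nrow(design)
  libFac <- exp(runif(nS, -log(config$libSizeRange) / 2,
                      log(config$libSizeRange) / 2))
  blockFac <- matrix(1, max(1L, config$nBlocks), nS)
  if (config$nBlocks > 0L && config$blockSd > 0) {
    blockFac[] <- stats::rlnorm(length(blockFac),
                                meanlog = -config$blockSd^2 / 2,
                                sdlog = config$blockSd)
    # balance the latent factor within each tissue's replicates so that
    # co-expression blocks stay orthogonal to the tissue axis: block
    # membership must not fake tissue specificity
    for (t in tissues) {
      sel <- design$tissue == t
      blockFac[, sel] <- blockFac[, sel, drop = FALSE] /
        rowMeans(blockFac[, sel, drop = FALSE])
    }
  }
  ids <- truth$transcript_id
  len <- lengths[ids]
  if (anyNA(len)) stop("truth and lengths disagree")
  ratio <- ifelse(truth$true_class == "coding", 1, config$lncExprRatio)
  base <- config$baselineMean * ratio * (len / 1000)
  counts <- matrix(0L, length(ids), nS,
                   dimnames = list(ids, design$sample_id))
  for (s in seq_len(nS)) {
    mult <- ifelse(!is.na(truth$true_specific_tissue) &
                     truth$true_specific_tissue == design$tissue[s],
                   config$specificityFold, 1)
    bf <- ifelse(is.na(truth$coexpression_block), 1,
                 blockFac[pmax(truth$coexpression_block, 1L), s])
    mu <- base * mult * bf * libFac[s]
    counts[, s] <- if (config$dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    }
  }
  low <- which(truth$true_class == "decoy_low_support")
  for (i in low) {
    tot <- sample(0:5, 1L)
    counts[i, ] <- as.integer(stats::rmultinom(1L, tot, rep(1, nS)))
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, design = design)
}

#' Simulate a gene-to-term annotation map
#'
#' Background GO-BP and KEGG terms are assigned uniformly at random to
#' coding genes; each co-expression block's planted terms are attached to
#' its coding members at `plantedFraction` and to non-members at
#' `backgroundTermRate`. Deterministic under `seed`.
#'
#' @param truth truth table from [simulateGenome()].
#' @param config an `lncSimConfig`.
#' @param seed term-map seed (default `config$seed + 2`).
#' @return a data.frame `gene_id`, `term_id`, `term_name`, `namespace`.
#' @export
simulateTermMap <- function(truth, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "lncSimConfig"))
  set.seed(seed)
  cod <- truth[truth$true_class == "coding", ]
  genes <- cod$gene_id
  bpTerms <- sprintf("GO:BG%04d", seq_len(config$nTermsBP))
  keggTerms <- sprintf("koBG%03d", seq_len(config$nTermsKEGG))
  rows <- list()
  for (i in seq_along(genes)) {
    tb <- sample(bpTerms, min(config$termsPerGene, length(bpTerms)))
    tk <- sample(keggTerms, min(max(1L, config$termsPerGene - 1L),
                                length(keggTerms)))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = genes[i], term_id = c(tb, tk),
      namespace = c(rep("BP", length(tb)), rep("KEGG", length(tk))),
      stringsAsFactors = FALSE)
  }
  tm <- do.call(rbind, rows)
  planted <- list()
  for (b in seq_len(config$nBlocks)) {
    bp <- sprintf("GO:PLANT%02d", b)
    kg <- sprintf("koPLANT%02d", b)
    member <- !is.na(cod$coexpression_block) & cod$coexpression_block == b
    getsBp <- (member & runif(nrow(cod)) < config$plantedFraction) |
      (!member & runif(nrow(cod)) < config$backgroundTermRate)
    getsKg <- (member & runif(nrow(cod)) < config$plantedFraction) |
      (!member & runif(nrow(cod)) < config$backgroundTermRate)
    if (any(getsBp)) planted[[length(planted) + 1L]] <- data.frame(
      gene_id = genes[getsBp], term_id = bp, namespace = "BP",
      stringsAsFactors = FALSE)
    if (any(getsKg)) planted[[length(planted) + 1L]] <- data.frame(
      gene_id = genes[getsKg], term_id = kg, namespace = "KEGG",
      stringsAsFactors = FALSE)
  }
  tm <- rbind(tm, do.call(rbind, planted))
  tm <- unique(tm)
  tm$term_name <- ifelse(grepl("PLANT", tm$term_id),
                         paste0("planted process ", sub(".*PLANT", "", tm$term_id)),
                         paste0("background process ", sub(".*(BG)", "", tm$term_id)))
  tm[, c("gene_id", "term_id", "term_name", "namespace")]
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulateGenome()], [simulateCounts()] and
#' [simulateTermMap()] under one config.
#'
#' @param config an `lncSimConfig` (default [simulationConfig()]).
#' @return a list: `seqs`, `annotation`, `truth`, `counts`, `design`,
#'   `termMap`, `config`.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  g <- simulateGenome(config)
  cc <- simulateCounts(g$truth, txLengths(g$annotation), config)
  tm <- simulateTermMap(g$truth, config)
  list(seqs = g$seqs, annotation = g$annotation, truth = g$truth,
       counts = cc$counts, design = cc$design, termMap = tm,
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes `genome.fa`, `transcripts.gtf`, `counts.tsv`, `design.tsv`,
#' `terms.tsv` and `truth.tsv` into a directory, in the same formats the
#' reading functions accept.
#'
#' @param sim list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$seqs, file.path(dir, "genome.fa"))
  writeTranscriptGtf(sim$annotation, file.path(dir, "transcripts.gtf"))
  cdf <- data.frame(transcript_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$termMap, file.path(dir, "terms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
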