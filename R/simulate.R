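#' @include AllClasses.R annotation.R io.R
#' @importFrom stats rlnorm rpois runif rnbinom rnorm
NULL

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators with defaults
#' that reproduce the statistical structure the analyses assume: log-normal
#' transcript region lengths, shared per-gene abundance variation,
#' AUG-proximal 5'-UTR CLIP enrichment on target genes over a uniform mature-
#' mRNA background with a 1% control library, ribosome footprints with
#' initiation/termination ramps and post-stop drop-off plus condition
#' multipliers for the mutant, negative-binomial expression replicates, and
#' PMS/PRS labeling courses with a configurable half-transit lag. Scale
#' defaults (300 genes, ~1e5 IP reads via a 0.2 reads/nt background, 1e5
#' footprints per condition) keep a full pipeline run on a desktop CPU while
#' preserving the signal-to-noise regime.
#'
#' @param seed integer seed (mandatory); all generators derive their streams
#'   from it.
#' @param nGenes number of protein-coding genes (default 300).
#' @param targetFraction fraction of coding genes bound by the protein
#'   (default 0.1).
#' @param nNcrna,nPseudo non-coding and pseudogene loci added so those
#'   genomic classes exist (default 10 each).
#' @param intronProb probability a coding gene carries one intron inside its
#'   CDS (default 0.5).
#' @param lengths list of log-normal `c(meanlog, sdlog)` for `utr5`, `cds`,
#'   `utr3`, `intron`, `ncrna`.
#' @param abundanceSdlog sdlog of the per-gene abundance factor shared by
#'   CLIP replicates, control and footprints (default 1; mean normalized
#'   to 1).
#' @param clip list: `backgroundRate` (IP reads per nt of mature transcript,
#'   default 0.2), `enrichmentFold` (default 10), `augWindow` (enriched
#'   window = last this many nt of the 5'-UTR, default 50),
#'   `controlDepthRatio` (default 0.01, echoing the deep IP / shallow IgG
#'   asymmetry), `readLength` (40), `nReplicates` (2).
#' @param ribo list: `nFootprints` per condition (1e5), `psiteOffset` (12),
#'   `readLength` (30), `utr5Rate` (5'-UTR rate relative to CDS plateau,
#'   0.5), `rampFold` (initiation/termination pile-up fold, 3), `rampFrac`
#'   (ramp width as fraction of CDS, 0.05), `dropFactor` (3'-UTR rate
#'   relative to plateau, 0.05), `conditions` (named list of
#'   `c(utr5_mult, cds_mult)`; default vector/WT at 1,1 and G325E at 3,0.6 —
#'   the multipliers apply to targets and non-targets alike).
#' @param expression list: `meanlog`/`sdlog` of gene mean counts (log(300),
#'   1), `dispersion` (NB dispersion, 0.02; cell-line replicate regime), `nReplicates` (3), `conditions`
#'   (default `c("ctrl", "treat")`).
#' @param transit list: `halfTransit` named minutes per condition (default
#'   1.5 for all three), `slope` (CPM/min, 500), `cv` (multiplicative noise
#'   CV, 0.05), `times` (minutes, 2..7), `nReplicates` (4).
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(seed,
                      nGenes = 300, targetFraction = 0.1,
                      nNcrna = 10, nPseudo = 10, intronProb = 0.5,
                      lengths = list(), abundanceSdlog = 1,
                      clip = list(), ribo = list(), expression = list(),
                      transit = list()) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory")
  defLengths <- list(utr5 = c(meanlog = log(150), sdlog = 0.5),
                     cds = c(meanlog = log(1200), sdlog = 0.5),
                     utr3 = c(meanlog = log(400), sdlog = 0.6),
                     intron = c(meanlog = log(800), sdlog = 0.5),
                     ncrna = c(meanlog = log(800), sdlog = 0.5))
  defClip <- list(backgroundRate = 0.2, enrichmentFold = 10, augWindow = 50,
                  controlDepthRatio = 0.01, readLength = 40L, nReplicates = 2L)
  defRibo <- list(nFootprints = 1e5, psiteOffset = 12L, readLength = 30L,
                  utr5Rate = 0.5, rampFold = 3, rampFrac = 0.05,
                  dropFactor = 0.05,
                  conditions = list(vector = c(utr5_mult = 1, cds_mult = 1),
                                    WT = c(utr5_mult = 1, cds_mult = 1),
                                    G325E = c(utr5_mult = 3, cds_mult = 0.6)))
  defExpr <- list(meanlog = log(300), sdlog = 1, dispersion = 0.02,
                  nReplicates = 3L, conditions = c("ctrl", "treat"))
  defTransit <- list(halfTransit = c(vector = 1.5, WT = 1.5, G325E = 1.5),
                     slope = 500, cv = 0.05, times = c(2, 3, 4, 5, 6, 7),
                     nReplicates = 4L)
  cfg <- list(seed = as.integer(seed %% 2^31), nGenes = as.integer(nGenes),
              targetFraction = targetFraction, nNcrna = as.integer(nNcrna),
              nPseudo = as.integer(nPseudo), intronProb = intronProb,
              lengths = utils::modifyList(defLengths, lengths),
              abundanceSdlog = abundanceSdlog,
              clip = utils::modifyList(defClip, clip),
              ribo = utils::modifyList(defRibo, ribo),
              expression = utils::modifyList(defExpr, expression),
              transit = utils::modifyList(defTransit, transit))
  with(cfg, {
    if (nGenes < 0 || targetFraction < 0 || targetFraction > 1)
      stop("invalid gene counts or target fraction")
    if (clip$backgroundRate < 0 || clip$enrichmentFold < 0 ||
        clip$controlDepthRatio < 0)
      stop("CLIP rates must be non-negative")
    if (any(vapply(ribo$conditions, function(x) any(x <= 0), TRUE)))
      stop("condition multipliers must be positive")
    if (any(vapply(lengths, function(x) x["sdlog"] < 0, TRUE)))
      stop("degenerate length distribution")
    if (transit$cv < 0) stop("transit noise CV must be non-negative")
  })
  class(cfg) <- "SimConfig"
  cfg
}

.deriveSeed <- function(cfg, k) (cfg$seed + k) %% 2147483647L

#' Simulate a transcript annotation
#'
#' Lays out `nGenes` coding genes (log-normal 5'-UTR/CDS/3'-UTR lengths, CDS
#' rounded to a codon multiple, optionally one intron inside the CDS) plus
#' ncRNA and pseudogene loci along one chromosome with 3 kb intergenic gaps,
#' alternating strands. Reproducible per seed.
#'
#' @param cfg a [simConfig()] object.
#' @return A [TranscriptAnnotation-class].
#' @export
simulateAnnotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(.deriveSeed(cfg, 0L))
  n <- cfg$nGenes
  ln <- cfg$lengths
  rl <- function(p, m) pmax(round(rlnorm(m, p["meanlog"], p["sdlog"])), 1)
  u5 <- rl(ln$utr5, n)
  cds <- pmax(round(rl(ln$cds, n) / 3), 34) * 3
  u3 <- rl(ln$utr3, n)
  hasIntron <- runif(n) < cfg$intronProb
  intronLen <- ifelse(hasIntron, rl(ln$intron, n), 0)
  ncLen <- rl(ln$ncrna, cfg$nNcrna)
  psLen <- rl(ln$ncrna, cfg$nPseudo)

  gap <- 3000
  cur <- gap
  rows <- list()
  bStart <- numeric(); bEnd <- numeric(); bTx <- character()
  addGene <- function(i, kind, txLen, iLen, u5i, cdsi, u3i, st) {
    id <- sprintf("t%04d", i); gid <- sprintf("g%04d", i)
    if (iLen > 0) {
      ## intron splits the transcript at the CDS midpoint (codon-aligned)
      cut <- u5i + 3 * floor(cdsi / 6)
      bStart <<- c(bStart, cur + 1, cur + cut + iLen + 1)
      bEnd <<- c(bEnd, cur + cut, cur + txLen + iLen)
      bTx <<- c(bTx, id, id)
    } else {
      bStart <<- c(bStart, cur + 1); bEnd <<- c(bEnd, cur + txLen)
      bTx <<- c(bTx, id)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = gid, chrom = "chr1", strand = st,
      utr5_len = u5i, cds_len = cdsi, utr3_len = u3i, gene_type = kind,
      stringsAsFactors = FALSE)
    cur <<- cur + txLen + iLen + gap
  }
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    st <- if (i %% 2 == 1) "+" else "-"
    addGene(k, "protein_coding", u5[i] + cds[i] + u3[i], intronLen[i],
            u5[i], cds[i], u3[i], st)
  }
  for (i in seq_len(cfg$nNcrna)) {
    k <- k + 1L
    addGene(k, "ncRNA", ncLen[i], 0, 0, 0, 0, if (k %% 2 == 1) "+" else "-")
  }
  for (i in seq_len(cfg$nPseudo)) {
    k <- k + 1L
    addGene(k, "pseudogene", psLen[i], 0, 0, 0, 0,
            if (k %% 2 == 1) "+" else "-")
  }
  txdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               utr5_len = numeric(), cds_len = numeric(),
               utr3_len = numeric(), gene_type = character())
  blocks <- if (length(bTx)) {
    g <- GRanges("chr1", IRanges(bStart, bEnd))
    S4Vectors::split(g, factor(bTx, levels = unique(bTx)))
  } else GRangesList()
  makeTranscriptAnnotation(txdf, blocks)
}

## shared per-gene abundance factors (mean 1), aligned with transcript order
.abundance <- function(cfg, anno) {
  set.seed(.deriveSeed(cfg, 2L))
  n <- nrow(anno@transcripts)
  a <- rlnorm(n, 0, cfg$abundanceSdlog)
  a / exp(cfg$abundanceSdlog^2 / 2)
}

## deterministic target gene sample (coding genes with a usable 5'-UTR)
.sampleTargets <- function(cfg, anno) {
  tx <- anno@transcripts
  eligible <- tx$gene_id[tx$cds_len > 0 & tx$utr5_len >= 20]
  set.seed(.deriveSeed(cfg, 1L))
  nT <- round(cfg$targetFraction * sum(tx$cds_len > 0))
  sort(sample(eligible, min(nT, length(eligible))))
}


#' Simulate CLIP IP replicates, the IgG control and the bound-gene truth
#'
#' Reads are placed on mature transcripts only: a uniform background at
#' `backgroundRate * abundance` reads/nt on every transcript, plus, on
#' target genes, an enrichment component at `(enrichmentFold - 1)` times the
#' background rate confined to the AUG-proximal window (the last
#' `augWindow` nt of the 5'-UTR). The control is uniform at
#' `controlDepthRatio` times the background depth. Per-gene abundance
#' factors are shared between replicates and control, which is what makes
#' biological replicates correlate.
#'
#' @param cfg a [simConfig()] object.
#' @param anno the matching [TranscriptAnnotation-class].
#' @param seed optional override of the read-placement seed (the abundance
#'   factors and target sample stay tied to `cfg$seed`).
#' @return list with `ip` (list of [ReadSet-class] replicates), `control`
#'   ([ReadSet-class]), `targets` (character), `truth` (data.frame
#'   `gene_id`, `bound`).
#' @export
simulateClip <- function(cfg, anno, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"), is(anno, "TranscriptAnnotation"))
  tx <- anno@transcripts
  a <- .abundance(cfg, anno)
  targets <- .sampleTargets(cfg, anno)
  cl <- cfg$clip
  base <- if (is.null(seed)) .deriveSeed(cfg, 10L)
          else as.integer(seed %% 2147483647)

  drawSet <- function(rate, enrich, sid, sd) {
    set.seed(sd)
    offs <- vector("list", nrow(tx)); ids <- vector("list", nrow(tx))
    for (i in seq_len(nrow(tx))) {
      L <- tx$tx_len[i]
      r <- rate * a[i]
      nBg <- rpois(1, r * L)
      off <- if (nBg) sample.int(L, nBg, replace = TRUE) - 1 else numeric()
      if (enrich && tx$gene_id[i] %in% targets) {
        w <- min(cl$augWindow, tx$utr5_len[i])
        nEn <- rpois(1, r * (cl$enrichmentFold - 1) * w)
        if (nEn)
          off <- c(off, tx$utr5_len[i] - w +
                        sample.int(w, nEn, replace = TRUE) - 1)
      }
      if (length(off)) {
        offs[[i]] <- off
        ids[[i]] <- rep(tx$transcript_id[i], length(off))
      }
    }
    off <- unlist(offs); id <- unlist(ids)
    g <- if (length(off))
      .txReadsToGenomic(anno, id, off, rep(cl$readLength, length(off)))
    else GRanges()
    ReadSet(sid, g)
  }
  ip <- lapply(seq_len(cl$nReplicates), function(r)
    drawSet(cl$backgroundRate, TRUE, sprintf("ip_rep%d", r), base + r))
  control <- drawSet(cl$backgroundRate * cl$controlDepthRatio, FALSE,
                     "igg_control", base + 100L)
  codingGenes <- tx$gene_id[tx$cds_len > 0]
  list(ip = ip, control = control, targets = targets,
       truth = data.frame(gene_id = codingGenes,
                          bound = codingGenes %in% targets))
}

#' Simulate ribosome footprints for one condition
#'
#' P-site anchors are drawn from a piecewise-constant rate over each coding
#' transcript: 5'-UTR at `utr5Rate * utr5_mult`, CDS plateau at `cds_mult`
#' with `rampFold` pile-ups over the first and last `rampFrac` of the CDS
#' (initiation/termination), and 3'-UTR at `plateau * dropFactor`
#' (post-stop drop-off). The mutant's multipliers apply to target and
#' non-target genes alike. Reads start `psiteOffset` nt 5' of the anchor;
#' anchors too close to the cap to leave room for the offset are dropped.
#'
#' @inheritParams simulateClip
#' @param condition name of a condition in `cfg$ribo$conditions`.
#' @return A [ReadSet-class] with `sampleId = condition`.
#' @export
simulateRibo <- function(cfg, anno, condition, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"), is(anno, "TranscriptAnnotation"))
  rb <- cfg$ribo
  if (!condition %in% names(rb$conditions))
    stop("unknown condition: ", condition)
  mult <- rb$conditions[[condition]]
  if (is.null(names(mult))) names(mult) <- c("utr5_mult", "cds_mult")
  tx <- anno@transcripts
  a <- .abundance(cfg, anno)
  coding <- which(tx$cds_len > 0)
  sd0 <- if (is.null(seed))
    .deriveSeed(cfg, 200L + match(condition, names(rb$conditions)))
  else as.integer(seed %% 2147483647)
  set.seed(sd0)

  u5 <- tx$utr5_len[coding]; cds <- tx$cds_len[coding]; u3 <- tx$utr3_len[coding]
  nRamp <- pmax(1, round(rb$rampFrac * cds))
  w5 <- u5 * rb$utr5Rate * mult["utr5_mult"]
  ## the initiation pile-up is a queue at the start codon, not elongating
  ## flux: it keeps the baseline rate while plateau, termination ramp and
  ## 3'-UTR runoff scale with cds_mult
  wInit <- rb$rampFold * nRamp
  wPlat <- mult["cds_mult"] * (cds - 2 * nRamp)
  wTerm <- mult["cds_mult"] * rb$rampFold * nRamp
  w3 <- u3 * rb$dropFactor * mult["cds_mult"]
  gw <- a[coding] * (w5 + wInit + wPlat + wTerm + w3)
  if (length(coding) == 0L || sum(gw) <= 0)
    return(ReadSet(condition, GRanges()))
  nPer <- as.vector(stats::rmultinom(1, rb$nFootprints, gw))

  offs <- vector("list", length(coding)); ids <- vector("list", length(coding))
  for (k in seq_along(coding)) {
    n <- nPer[k]
    if (n == 0) next
    i <- coding[k]
    segW <- c(w5[k], wInit[k], wPlat[k], wTerm[k], w3[k])
    segLen <- c(u5[k], nRamp[k], cds[k] - 2 * nRamp[k], nRamp[k], u3[k])
    segStart <- cumsum(c(0, segLen))[1:5]
    seg <- sample.int(5, n, replace = TRUE, prob = pmax(segW, 0))
    anchors <- segStart[seg] + floor(runif(n) * segLen[seg])
    anchors <- anchors[anchors >= rb$psiteOffset]   # room for the read start
    if (!length(anchors)) next
    offs[[k]] <- anchors - rb$psiteOffset
    ids[[k]] <- rep(tx$transcript_id[i], length(anchors))
  }
  off <- unlist(offs); id <- unlist(ids)
  g <- if (length(off))
    .txReadsToGenomic(anno, id, off, rep(rb$readLength, length(off)))
  else GRanges()
  ReadSet(condition, g)
}

#' Simulate a replicated negative-binomial expression table
#'
#' Gene mean counts are log-normal and identical across conditions unless a
#' per-gene `log2Shift` is supplied for the second condition — matching the
#' observation that neither knockdown nor mutant expression changed target
#' mRNA abundance.
#'
#' @inheritParams simulateClip
#' @param log2Shift optional named numeric of per-gene log2 fold changes
#'   applied to the second condition.
#' @return list with `expr` (genes x samples count matrix, columns
#'   `<condition>_<rep>`) and `condition` labels.
#' @export
simulateExpression <- function(cfg, anno, log2Shift = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"), is(anno, "TranscriptAnnotation"))
  ex <- cfg$expression
  tx <- anno@transcripts
  genes <- tx$gene_id[tx$cds_len > 0]
  set.seed(.deriveSeed(cfg, 3L))
  mu <- rlnorm(length(genes), ex$meanlog, ex$sdlog)
  set.seed(if (is.null(seed)) .deriveSeed(cfg, 4L)
           else as.integer(seed %% 2147483647))
  conds <- ex$conditions
  cols <- list(); labels <- character()
  for (ci in seq_along(conds)) {
    sh <- rep(0, length(genes))
    if (ci == 2L && !is.null(log2Shift)) {
      j <- match(names(log2Shift), genes)
      sh[j[!is.na(j)]] <- log2Shift[!is.na(j)]
    }
    for (r in seq_len(ex$nReplicates)) {
      cols[[length(cols) + 1L]] <-
        rnbinom(length(genes), mu = mu * 2^sh, size = 1 / ex$dispersion)
      labels <- c(labels, sprintf("%s_%d", conds[ci], r))
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(genes, labels)
  list(expr = m, condition = sub("_[^_]*$", "", labels))
}

#' Simulate PMS/PRS labeling time courses
#'
#' `pms(t) = slope * t * (1 + e)` and
#' `prs(t) = slope * max(0, t - halfTransit) * (1 + e)` with multiplicative
#' Gaussian noise `e ~ N(0, cv^2)` per point; with `cv = 0` the configured
#' half-transit time is recovered exactly by [fitHalfTransit()].
#'
#' @inheritParams simulateClip
#' @return data.frame with columns `condition`, `replicate`, `time_min`,
#'   `pms_cpm`, `prs_cpm`.
#' @export
simulateTransit <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  tr <- cfg$transit
  set.seed(if (is.null(seed)) .deriveSeed(cfg, 5L)
           else as.integer(seed %% 2147483647))
  rows <- list()
  for (cd in names(tr$halfTransit)) {
    tau <- tr$halfTransit[[cd]]
    for (r in seq_len(tr$nReplicates)) {
      t <- tr$times
      pms <- tr$slope * t * (1 + rnorm(length(t), 0, tr$cv))
      prs <- tr$slope * pmax(0, t - tau) * (1 + rnorm(length(t), 0, tr$cv))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cd, replicate = r, time_min = t,
        pms_cpm = pmax(pms, 0), prs_cpm = pmax(prs, 0))
    }
  }
  do.call(rbind, rows)
}
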