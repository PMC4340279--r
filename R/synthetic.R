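# Seeded generator of paired two-class mRNA/microRNA studies with planted
# differential signal, disease-biased term collections, a seed-gene list
# and a validated-style target map. The generation sequence is fixed and
# documented in simulateStudy() so a given config + seed is reproducible
# bit for bit.

#' Configuration for a synthetic paired expression study
#'
#' Defaults describe the test-scale study used throughout the package's
#' examples and tests: 30 + 30 samples, 500 genes, 60 microRNAs, four term
#' collections of 20 terms, a 1.5-standard-deviation planted mean shift.
#' The shape mirrors a two-class case-control microarray design with an
#' mRNA and a mature-microRNA layer measured on the same individuals.
#'
#' @param nPos,nNeg samples in the positive (case) / negative (control)
#'   class.
#' @param nGenes,nMirnas features per layer.
#' @param fracDeGenes,fracDeMirnas fraction of features planted as
#'   differential, in `[0, 1]`.
#' @param effectSize mean shift of planted features in the case class, in
#'   units of the within-class standard deviation (which is 1).
#' @param nTerms terms per collection; `termSizeRange` inclusive bounds on
#'   term sizes.
#' @param nDiseaseTerms terms per collection planted as disease-associated
#'   (members drawn preferentially from seed and planted genes).
#' @param diseaseTermPurity probability that a disease-term member is drawn
#'   from the seed-or-planted pool rather than uniformly.
#' @param nSeedGenes size of the disease seed-gene list.
#' @param seedEnrichmentBias probability a seed gene is drawn from the
#'   planted differential genes.
#' @param nTargetPairs unique microRNA-gene pairs in the target map.
#' @param targetBias probability a pair whose microRNA is planted targets a
#'   seed gene.
#' @param rngSeed integer seed driving all randomness.
#' @return A validated list of class `simulationConfig`.
#' @examples
#' cfg <- simulationConfig(nPos = 20, nNeg = 10, nGenes = 50, nMirnas = 10)
#' study <- simulateStudy(cfg)
#' study
#' @export
simulationConfig <- function(nPos = 30L, nNeg = 30L, nGenes = 500L,
                             nMirnas = 60L, fracDeGenes = 0.1,
                             fracDeMirnas = 0.15, effectSize = 1.5,
                             nTerms = 20L, termSizeRange = c(5L, 25L),
                             nDiseaseTerms = 4L, diseaseTermPurity = 0.8,
                             nSeedGenes = 40L, seedEnrichmentBias = 0.9,
                             nTargetPairs = 300L, targetBias = 0.9,
                             rngSeed = 1L) {
  cfg <- list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
              nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
              fracDeGenes = fracDeGenes, fracDeMirnas = fracDeMirnas,
              effectSize = effectSize, nTerms = as.integer(nTerms),
              termSizeRange = as.integer(termSizeRange),
              nDiseaseTerms = as.integer(nDiseaseTerms),
              diseaseTermPurity = diseaseTermPurity,
              nSeedGenes = as.integer(nSeedGenes),
              seedEnrichmentBias = seedEnrichmentBias,
              nTargetPairs = as.integer(nTargetPairs),
              targetBias = targetBias, rngSeed = as.integer(rngSeed))
  counts <- cfg[c("nPos", "nNeg", "nGenes", "nMirnas", "nTerms",
                  "nDiseaseTerms", "nSeedGenes", "nTargetPairs")]
  if (any(unlist(counts) <= 0L)) stop("all counts must be positive")
  fr <- cfg[c("fracDeGenes", "fracDeMirnas", "diseaseTermPurity",
              "seedEnrichmentBias", "targetBias")]
  if (any(unlist(fr) < 0 | unlist(fr) > 1))
    stop("fractions and probabilities must lie in [0, 1]")
  if (cfg$effectSize < 0) stop("effectSize must be >= 0")
  if (cfg$fracDeGenes * cfg$nGenes < 1 || cfg$fracDeMirnas * cfg$nMirnas < 1)
    stop("planted fraction times feature count must be at least 1")
  if (cfg$termSizeRange[1L] < 1L || cfg$termSizeRange[2L] < cfg$termSizeRange[1L])
    stop("termSizeRange must be increasing and positive")
  if (cfg$nDiseaseTerms > cfg$nTerms)
    stop("nDiseaseTerms cannot exceed nTerms")
  if (cfg$nSeedGenes > cfg$nGenes) stop("nSeedGenes cannot exceed nGenes")
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate a paired two-class mRNA/microRNA study
#'
#' Expression is class-conditional Gaussian on a log-intensity-like scale:
#' each feature has baseline mean mu_f ~ Normal(7, 2^2) and unit
#' within-class standard deviation; planted differential features gain an
#' additive `effectSize` shift in the case class. Seed genes are drawn from
#' the planted genes with probability `seedEnrichmentBias`; each collection
#' plants `nDiseaseTerms` disease terms whose members come from the
#' seed-or-planted pool with probability `diseaseTermPurity`; target pairs
#' whose microRNA is planted point at a seed gene with probability
#' `targetBias`. All draws come from one RNG stream seeded by
#' `cfg$rngSeed`, in the fixed order: labels, mRNA layer, microRNA layer,
#' seed genes, collections (BP, MF, CC, Pathway), target map.
#'
#' @param cfg a [simulationConfig()].
#' @return A [SyntheticStudy-class] object.
#' @export
simulateStudy <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  withSeed(cfg$rngSeed, {
    nS <- cfg$nPos + cfg$nNeg
    sampleIds <- sprintf("S%03d", seq_len(nS))
    labels <- setNames(factor(rep(c("case", "control"),
                                  c(cfg$nPos, cfg$nNeg)),
                              levels = c("control", "case")), sampleIds)
    caseCol <- labels == "case"

    simLayer <- function(prefix, nF, fracDe) {
      ids <- sprintf("%s%04d", prefix, seq_len(nF))
      nDe <- max(1L, floor(fracDe * nF))
      de <- sort(sample(ids, nDe))
      mu <- rnorm(nF, mean = 7, sd = 2)
      m <- matrix(rnorm(nF * nS, mean = mu, sd = 1), nrow = nF,
                  dimnames = list(ids, sampleIds))
      if (length(de))
        m[de, caseCol] <- m[de, caseCol] + cfg$effectSize
      list(mat = m, de = de)
    }
    mrna <- simLayer("G", cfg$nGenes, cfg$fracDeGenes)
    mirna <- simLayer("M", cfg$nMirnas, cfg$fracDeMirnas)
    geneIds <- rownames(mrna$mat)
    mirIds <- rownames(mirna$mat)

    nFromDe <- min(rbinom(1L, cfg$nSeedGenes, cfg$seedEnrichmentBias),
                   length(mrna$de))
    seedGenes <- sort(c(
      sample(mrna$de, nFromDe),
      sample(setdiff(geneIds, mrna$de), cfg$nSeedGenes - nFromDe)))

    diseasePool <- union(seedGenes, mrna$de)
    makeCollection <- function(name) {
      sizes <- sample(seq(cfg$termSizeRange[1L], cfg$termSizeRange[2L]),
                      cfg$nTerms, replace = TRUE)
      sets <- vector("list", cfg$nTerms)
      names(sets) <- sprintf("%s:%04d", name, seq_len(cfg$nTerms))
      for (i in seq_len(cfg$nTerms)) {
        sz <- min(sizes[i], length(geneIds))
        if (i <= cfg$nDiseaseTerms) {
          nPool <- min(rbinom(1L, sz, cfg$diseaseTermPurity),
                       length(diseasePool))
          sets[[i]] <- unique(c(
            sample(diseasePool, nPool),
            sample(setdiff(geneIds, diseasePool), sz - nPool)))
        } else {
          sets[[i]] <- sample(geneIds, sz)
        }
      }
      AnnotationCollection(name, sets, universe = geneIds)
    }
    collections <- list(BP = makeCollection("BP"), MF = makeCollection("MF"),
                        CC = makeCollection("CC"),
                        Pathway = makeCollection("Pathway"))
    diseaseTerms <- lapply(collections, function(cl)
      names(geneSets(cl))[seq_len(cfg$nDiseaseTerms)])

    drawPairs <- function(k) {
      mir <- sample(mirIds, k, replace = TRUE)
      planted <- mir %in% mirna$de
      useSeed <- planted & runif(k) < cfg$targetBias
      gene <- character(k)
      gene[useSeed] <- sample(seedGenes, sum(useSeed), replace = TRUE)
      gene[!useSeed] <- sample(geneIds, sum(!useSeed), replace = TRUE)
      data.frame(mirna = mir, gene = gene, stringsAsFactors = FALSE)
    }
    pairs <- unique(drawPairs(cfg$nTargetPairs))
    tries <- 0L
    while (nrow(pairs) < cfg$nTargetPairs && tries < 50L) {
      pairs <- unique(rbind(pairs, drawPairs(cfg$nTargetPairs - nrow(pairs))))
      tries <- tries + 1L
    }
    pairs <- pairs[seq_len(min(nrow(pairs), cfg$nTargetPairs)), ]

    new("SyntheticStudy", mrna = mrna$mat, mirna = mirna$mat,
        labels = labels, collections = collections, seedGenes = seedGenes,
        targetMap = TargetMap(pairs),
        truth = list(deGenes = mrna$de, deMirnas = mirna$de,
                     diseaseTerms = diseaseTerms),
        config = unclass(cfg))
  })
}

#' Write a synthetic study to disk in the package's file formats
#'
#' Emits the mRNA and microRNA expression TSVs, the label TSV, one GMT per
#' collection, the seed-gene list, the target-map TSV and a JSON truth
#' record of the planted structure, and returns a manifest of paths and
#' record counts.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return data.frame manifest: `artifact`, `path`, `records`.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mrna = file.path(dir, "mrna_expression.tsv"),
    mirna = file.path(dir, "mirna_expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    seed_genes = file.path(dir, "seed_genes.txt"),
    target_map = file.path(dir, "target_map.tsv"),
    truth = file.path(dir, "truth.json"))
  writeExpressionMatrix(study@mrna, paths$mrna)
  writeExpressionMatrix(study@mirna, paths$mirna)
  writeSampleLabels(study@labels, paths$labels)
  writeSeedGenes(study@seedGenes, paths$seed_genes)
  writeTargetMap(study@targetMap, paths$target_map)
  jsonlite::write_json(study@truth, paths$truth, auto_unbox = FALSE)
  records <- c(mrna = nrow(study@mrna), mirna = nrow(study@mirna),
               labels = length(study@labels),
               seed_genes = length(study@seedGenes),
               target_map = nrow(targetPairs(study@targetMap)),
               truth = length(study@truth$deGenes) +
                 length(study@truth$deMirnas))
  for (nm in names(study@collections)) {
    p <- file.path(dir, paste0("genesets_", nm, ".gmt"))
    writeGeneSets(study@collections[[nm]], p)
    paths[[paste0("gmt_", nm)]] <- p
    records[paste0("gmt_", nm)] <- length(geneSets(study@collections[[nm]]))
  }
  data.frame(artifact = names(paths), path = unlist(paths, use.names = FALSE),
             records = as.integer(records[names(paths)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
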