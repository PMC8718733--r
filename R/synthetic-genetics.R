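#' Generate correlated genotype dosages with a variant map
#'
#' Dosages in \{0, 1, 2\} are built from two latent Gaussian haplotypes per
#' individual. Variants are laid out in consecutive LD blocks; within a block
#' every haplotype shares a common factor with loading \code{sqrt(withinBlockR)},
#' so the latent correlation between any two variants of a block is
#' \code{withinBlockR} and zero across blocks. Each latent value is
#' thresholded at the variant's allele-frequency quantile, which preserves
#' Hardy-Weinberg marginals.
#'
#' @param n individuals.
#' @param m variants (>= 1).
#' @param ldBlockSize variants per LD block.
#' @param withinBlockR latent within-block correlation, in [0, 1).
#' @param mafRange uniform range the per-variant minor allele frequency is
#'   drawn from; must lie in (0, 0.5].
#' @param spacingBp base-pair distance between adjacent variants.
#' @param chromosome chromosome label assigned to all variants.
#' @param seed integer.
#' @return list: \code{dosages} (n x m integer matrix, columns named by
#'   variant id) and \code{variants} (data.frame: snp, chr, pos, ea, oa, eaf
#'   with eaf the empirical effect-allele frequency).
#' @examples
#' g <- generateGenotypes(100, 20, seed = 1)
#' dim(g$dosages)
#' @export
generateGenotypes <- function(n, m, ldBlockSize = 10L, withinBlockR = 0,
                              mafRange = c(0.05, 0.5), spacingBp = 50000L,
                              chromosome = 1L, seed = 1L) {
  if (m < 1L) stop("m must be >= 1")
  if (withinBlockR < 0 || withinBlockR >= 1)
    stop("withinBlockR must be in [0, 1)")
  if (mafRange[1L] <= 0 || mafRange[2L] > 0.5)
    stop("mafRange must lie in (0, 0.5]")
  old <- .Random.seed_exists(); set.seed(as.integer(seed))
  on.exit(.Random.seed_restore(old), add = TRUE)

  maf <- runif(m, mafRange[1L], mafRange[2L])
  block <- rep(seq_len(ceiling(m / ldBlockSize)), each = ldBlockSize)[seq_len(m)]
  lam <- sqrt(withinBlockR)
  hap <- function() {
    common <- matrix(rnorm(n * max(block)), n)[, block, drop = FALSE]
    z <- lam * common + sqrt(1 - withinBlockR) * matrix(rnorm(n * m), n, m)
    sweep(z, 2, qnorm(maf), "<") * 1L
  }
  dos <- hap() + hap()
  storage.mode(dos) <- "integer"
  snp <- sprintf("rs%06d", seq_len(m))
  colnames(dos) <- snp
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * m, replace = TRUE), ncol = 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- vapply(alleles[same, 1], function(a)
    sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1))
  list(
    dosages = dos,
    variants = data.frame(
      snp = snp, chr = as.integer(chromosome),
      pos = as.integer(seq_len(m)) * as.integer(spacingBp),
      ea = alleles[, 1], oa = alleles[, 2],
      eaf = colMeans(dos) / 2, stringsAsFactors = FALSE)
  )
}

#' Configuration for the two-sample summary-statistic simulator
#'
#' @param kInstruments number of independent instruments (>= 1).
#' @param betaExposureSD SD of the true per-variant exposure effects
#'   (per-SD units of an inverse-normal-transformed exposure).
#' @param theta causal effect of the exposure on the outcome (log odds per
#'   exposure SD for a binary outcome).
#' @param pleiotropyMode one of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}, \code{"inside_violating"}. Under \code{"none"} the
#'   pleiotropy term is identically zero, so the InSIDE assumption holds by
#'   construction. \code{"balanced"} adds N(0, pleiotropySD) direct effects,
#'   \code{"directional"} N(pleiotropyMean, pleiotropySD), and
#'   \code{"inside_violating"} makes the direct effect proportional to the
#'   instrument strength (correlated with the exposure effect).
#' @param pleiotropySD,pleiotropyMean direct-effect scale and mean.
#' @param nExposure,nOutcome GWAS sample sizes behind the two tables. The
#'   outcome default (20000) is an \emph{effective} sample size of the kind a
#'   binary outcome with low prevalence yields in a large cohort
#'   (4 p (1-p) N).
#' @param mafRange uniform range for minor allele frequencies, in (0, 0.5).
#' @param palindromicFraction fraction of variants assigned A/T or G/C
#'   allele pairs.
#' @param selectionZ instruments are lead variants that passed a
#'   genome-wide significance screen, so true effects are drawn conditional
#'   on detectability: \eqn{|\beta_X| > selectionZ \times SE}. The default
#'   5.45 corresponds to P < 5e-8; set 0 to disable the screen.
#' @param seed integer.
#' @return list of class \code{"mrSimConfig"}.
#' @export
mrSimConfig <- function(kInstruments, betaExposureSD = 0.05, theta = 0,
                        pleiotropyMode = c("none", "balanced", "directional",
                                           "inside_violating"),
                        pleiotropySD = 0, pleiotropyMean = 0,
                        nExposure = 30000L, nOutcome = 20000L,
                        mafRange = c(0.1, 0.4), palindromicFraction = 0.2,
                        selectionZ = 5.45, seed = 1L) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  if (kInstruments < 1L) stop("kInstruments must be >= 1")
  if (mafRange[1L] <= 0 || mafRange[2L] >= 0.5)
    stop("mafRange must lie strictly inside (0, 0.5)")
  structure(list(
    kInstruments = as.integer(kInstruments), betaExposureSD = betaExposureSD,
    theta = theta, pleiotropyMode = pleiotropyMode,
    pleiotropySD = pleiotropySD, pleiotropyMean = pleiotropyMean,
    nExposure = as.integer(nExposure), nOutcome = as.integer(nOutcome),
    mafRange = mafRange, palindromicFraction = palindromicFraction,
    selectionZ = selectionZ, seed = as.integer(seed)
  ), class = "mrSimConfig")
}

#' Simulate exposure and outcome GWAS summary statistics
#'
#' Per variant j: true exposure effect \eqn{\beta_{Xj} \sim |N(0, sd^2)|} --
#' effect alleles are reported for the exposure-increasing allele, as GWAS
#' lead variants are; estimated effects add sampling noise with
#' \eqn{SE = 1/\sqrt{2 p_j (1 - p_j) n}}. The true outcome effect is
#' \eqn{\theta \beta_{Xj} + \alpha_j} with the pleiotropy term set by the
#' configured mode, and the outcome estimate adds its own sampling noise.
#'
#' @param config an \code{\link{mrSimConfig}}.
#' @return list with \code{exposure} and \code{outcome} data.frames in the
#'   tab-delimited schema (SNP, CHR, BP, EA, OA, EAF, BETA, SE, P, N) and
#'   \code{truth} (per-variant true betaX and alpha).
#' @examples
#' ss <- generateMRSummaryStats(mrSimConfig(10, theta = 0.4, seed = 3))
#' head(ss$exposure)
#' @export
generateMRSummaryStats <- function(config) {
  stopifnot(inherits(config, "mrSimConfig"))
  old <- .Random.seed_exists(); set.seed(config$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  k <- config$kInstruments
  maf <- runif(k, config$mafRange[1L], config$mafRange[2L])
  seXj <- 1 / sqrt(2 * maf * (1 - maf) * config$nExposure)
  betaX <- vapply(seXj, function(se) {
    floor <- config$selectionZ * se
    for (i in seq_len(10000L)) {
      b <- abs(rnorm(1, 0, config$betaExposureSD))
      if (b > floor) return(b)
    }
    floor + abs(rnorm(1, 0, config$betaExposureSD))  # unreachable screen
  }, numeric(1))
  alpha <- switch(config$pleiotropyMode,
    none = rep(0, k),
    balanced = rnorm(k, 0, config$pleiotropySD),
    directional = rnorm(k, config$pleiotropyMean, config$pleiotropySD),
    inside_violating = 0.5 * abs(betaX) +
      rnorm(k, 0, config$pleiotropySD))
  seX <- seXj
  seY <- 1 / sqrt(2 * maf * (1 - maf) * config$nOutcome)
  bxHat <- betaX + rnorm(k, 0, seX)
  byHat <- config$theta * betaX + alpha + rnorm(k, 0, seY)

  nPal <- round(config$palindromicFraction * k)
  pal <- sample(k, nPal)
  ea <- oa <- character(k)
  pairs <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  for (j in seq_len(k)) {
    if (j %in% pal) {
      pr <- pairs[[sample(4, 1)]]
    } else {
      pr <- sample(c("A", "C", "G", "T"), 2)
      while (paste(sort(pr), collapse = "") %in% c("AT", "CG"))
        pr <- sample(c("A", "C", "G", "T"), 2)
    }
    ea[j] <- pr[1]; oa[j] <- pr[2]
  }
  mk <- function(beta, se, n) data.frame(
    SNP = sprintf("rs%06d", seq_len(k)), CHR = 1L,
    BP = seq_len(k) * 1000000L, EA = ea, OA = oa, EAF = maf,
    BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)), N = n,
    stringsAsFactors = FALSE)
  list(exposure = mk(bxHat, seX, config$nExposure),
       outcome = mk(byHat, seY, config$nOutcome),
       truth = data.frame(SNP = sprintf("rs%06d", seq_len(k)),
                          betaX = betaX, alpha = alpha))
}

#' Write / read GWAS summary statistics (tab-delimited)
#'
#' Schema: SNP, CHR, BP, EA, OA, EAF, BETA, SE, P, N.
#'
#' @param x data.frame in the schema above.
#' @param path file path.
#' @return \code{readSummaryStats} returns the data.frame.
#' @export
writeSummaryStats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSummaryStats
#' @export
readSummaryStats <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
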