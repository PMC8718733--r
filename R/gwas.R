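#' Variant-level filters: minor allele frequency and imputation quality
#'
#' Keeps variants with MAF >= 0.005 (frequency read symmetrically: an
#' effect-allele frequency of 0.996 is a MAF of 0.004) and, when an INFO
#' column is present and non-missing, INFO >= 0.3.
#'
#' @param records data.frame with \code{EAF} (or \code{eaf}) and optionally
#'   \code{INFO}/\code{info}.
#' @param mafMin,infoMin thresholds (defaults 0.005 and 0.3).
#' @return the filtered data.frame.
#' @export
filterVariants <- function(records, mafMin = 0.005, infoMin = 0.3) {
  eaf <- records$EAF
  if (is.null(eaf)) eaf <- records$eaf
  if (is.null(eaf)) stop("records need an EAF/eaf column")
  maf <- pmin(eaf, 1 - eaf)
  keep <- maf >= mafMin
  info <- records$INFO
  if (is.null(info)) info <- records$info
  if (!is.null(info)) keep <- keep & (is.na(info) | info >= infoMin)
  records[keep, , drop = FALSE]
}

#' Covariate-adjusted single-variant association (OLS)
#'
#' Ordinary least-squares regression of the phenotype on one dosage with
#' covariates included -- the desk-scale stand-in for a mixed-model engine,
#' appropriate for unrelated individuals. Returns the dosage term's effect,
#' SE and p.
#'
#' @param dosage numeric vector of allele dosages.
#' @param phenotype numeric vector (typically inverse-normal transformed).
#' @param covariates numeric matrix/data.frame (or NULL).
#' @return one-row data.frame: beta, se, t, p, n, plus \code{flag}
#'   (\code{"constant_dosage"} or \code{"collinear"} when the dosage carries
#'   no independent information; estimates are then NA).
#' @export
associateVariant <- function(dosage, phenotype, covariates = NULL) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & !apply(is.na(covariates), 1, any)
  }
  d <- dosage[ok]; yv <- phenotype[ok]
  n <- length(d)
  out <- data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, n = n, flag = "", stringsAsFactors = FALSE)
  if (var(d) == 0) { out$flag <- "constant_dosage"; return(out) }
  X <- cbind(intercept = 1, dosage = d,
             if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  if (n <= ncol(X)) stop("too few observations for the design")
  fit <- lm.fit(X, yv)
  if (fit$rank < ncol(X)) { out$flag <- "collinear"; return(out) }
  res <- fit$residuals
  dfres <- n - ncol(X)
  sigma2 <- sum(res^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  out$beta <- fit$coefficients[["dosage"]]
  out$se <- se
  out$t <- out$beta / se
  out$p <- 2 * pt(-abs(out$t), dfres)
  out
}

#' Association scan over a dosage matrix
#'
#' @param dosages n x m dosage matrix (columns named by variant).
#' @param phenotype numeric vector.
#' @param covariates matrix/data.frame or NULL.
#' @param variants optional variant map (data.frame with snp/chr/pos/ea/oa)
#'   merged onto the results.
#' @return data.frame with one row per variant: snp, beta, se, t, p, n,
#'   flag, eaf, and the map columns when supplied.
#' @export
associateAll <- function(dosages, phenotype, covariates = NULL,
                         variants = NULL) {
  res <- do.call(rbind, lapply(seq_len(ncol(dosages)), function(j)
    associateVariant(dosages[, j], phenotype, covariates)))
  res <- cbind(snp = colnames(dosages), res, eaf = colMeans(dosages) / 2,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (!is.null(variants))
    res <- merge(variants, res, by = "snp", sort = FALSE)
  res
}

#' Empirical LD matrix (squared Pearson correlation of dosages)
#'
#' @param dosages n x m dosage matrix.
#' @return m x m matrix of r^2 values.
#' @export
ldMatrix <- function(dosages) {
  r <- suppressWarnings(cor(dosages))
  r[!is.finite(r)] <- 0
  r^2
}

#' Greedy LD clumping
#'
#' Iterates variants passing the p-value threshold in order of ascending p
#' (ties broken by smaller position): each selected lead removes every
#' remaining variant with r^2 >= \code{r2Threshold} within the +/- 5 Mb
#' window. Leads reaching genome-wide significance are marked.
#'
#' @param associations data.frame with \code{snp}, \code{p}, \code{pos}
#'   (bp) and optionally \code{chr}.
#' @param r2 m x m matrix (dimnames by snp) or data.frame-free matrix in
#'   association order.
#' @param pThreshold inclusion threshold (default 1e-5).
#' @param r2Threshold LD cut-off (default 0.005).
#' @param windowBp half-width of the clumping window: leads remove linked
#'   variants within +/- windowBp (default 5e6).
#' @param genomewideP genome-wide significance mark (default 5e-8).
#' @return data.frame of lead variants (association rows) with an added
#'   \code{genomewideSignificant} logical, ordered by selection.
#' @export
greedyClump <- function(associations, r2, pThreshold = 1e-5,
                        r2Threshold = 0.005, windowBp = 5e6,
                        genomewideP = 5e-8) {
  a <- associations[!is.na(associations$p) & associations$p < pThreshold, ,
                    drop = FALSE]
  if (!nrow(a)) {
    out <- associations[0, , drop = FALSE]
    out$genomewideSignificant <- logical(0)
    return(out)
  }
  if (!is.null(dimnames(r2)))
    r2 <- r2[associations$snp, associations$snp, drop = FALSE]
  rownames(r2) <- colnames(r2) <- associations$snp
  a <- a[order(a$p, a$pos), , drop = FALSE]
  chr <- if (!is.null(a$chr)) a$chr else rep(1L, nrow(a))
  active <- rep(TRUE, nrow(a))
  leads <- integer(0)
  for (i in seq_len(nrow(a))) {
    if (!active[i]) next
    leads <- c(leads, i)
    linked <- active &
      chr == chr[i] &
      abs(a$pos - a$pos[i]) <= windowBp &
      r2[a$snp[i], a$snp] >= r2Threshold
    active[linked] <- FALSE
  }
  out <- a[leads, , drop = FALSE]
  out$genomewideSignificant <- out$p < genomewideP
  rownames(out) <- NULL
  out
}

#' Define and merge genetic loci around lead variants
#'
#' Each lead defines a +/- \code{flankBp} interval (1 Mb at either side by
#' default). Intervals from different traits that overlap on the same
#' chromosome are merged into one locus that keeps the lowest-p lead and
#' records the contributing traits -- the cross-trait consolidation into a
#' credible locus set.
#'
#' @param leadsByTrait named list of lead data.frames (columns snp, chr,
#'   pos, p) as returned by \code{\link{greedyClump}}.
#' @param flankBp flank size (default 1e6).
#' @return data.frame: leadSnp, chr, start, end (0-based half-open), leadP,
#'   traits (comma-joined), nLeads.
#' @export
defineLoci <- function(leadsByTrait, flankBp = 1e6) {
  if (is.data.frame(leadsByTrait)) leadsByTrait <- list(trait = leadsByTrait)
  all <- do.call(rbind, lapply(names(leadsByTrait), function(tr) {
    l <- leadsByTrait[[tr]]
    if (!nrow(l)) return(NULL)
    data.frame(snp = l$snp, chr = if (!is.null(l$chr)) l$chr else 1L,
               pos = l$pos, p = l$p, trait = tr, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all))
    return(data.frame(leadSnp = character(), chr = integer(),
                      start = numeric(), end = numeric(), leadP = numeric(),
                      traits = character(), nLeads = integer(),
                      stringsAsFactors = FALSE))
  all$start <- pmax(0, all$pos - flankBp)
  all$end <- all$pos + flankBp
  all <- all[order(all$chr, all$start), ]
  loci <- list()
  cur <- all[1, , drop = FALSE]
  curStart <- cur$start; curEnd <- cur$end
  members <- cur
  flush <- function(members, curStart, curEnd) {
    best <- members[which.min(members$p), ]
    data.frame(leadSnp = best$snp, chr = best$chr, start = curStart,
               end = curEnd, leadP = best$p,
               traits = paste(sort(unique(members$trait)), collapse = ","),
               nLeads = nrow(members), stringsAsFactors = FALSE)
  }
  if (nrow(all) > 1) for (i in 2:nrow(all)) {
    row <- all[i, , drop = FALSE]
    if (row$chr == members$chr[1] && row$start < curEnd) {
      members <- rbind(members, row)
      curEnd <- max(curEnd, row$end)
    } else {
      loci[[length(loci) + 1L]] <- flush(members, curStart, curEnd)
      members <- row; curStart <- row$start; curEnd <- row$end
    }
  }
  loci[[length(loci) + 1L]] <- flush(members, curStart, curEnd)
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square quantiles of the p-values divided by the
#' null median 0.4549: 1 under the uniform null, above 1 under inflation.
#'
#' @param p vector of p-values (>= 100 recommended).
#' @return lambda.
#' @examples
#' genomicLambda(rep(0.5, 200))  # exactly 1
#' @export
genomicLambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 2L) stop("need p-values")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
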