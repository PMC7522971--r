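#' @title Cis/trans phase inference from allele-specific amplicons
#' @description Models an allele-specific (RT-)PCR experiment: a primer
#' anchored on one allele of one site amplifies the molecule carrying that
#' allele, and the partner site's allele is read from the amplicon. In a
#' double heterozygote the two mutant alleles sit on opposite chromosomes
#' (trans) iff an alt-anchored amplicon shows the reference allele at the
#' partner site (and a ref-anchored amplicon shows the alternate). The
#' qualitative trace readout is generalised to counted observations with a
#' noise threshold.
#' @name phase
NULL

#' Build an amplicon observation table
#'
#' @param anchor_site,observed_site site identifiers (must differ per row)
#' @param anchor_allele,observed_allele "ref" or "alt"
#' @param read_support positive integer read/trace counts
#' @return data.frame of observations
#' @export
amplicon_observations <- function(anchor_site, anchor_allele,
                                  observed_site, observed_allele,
                                  read_support) {
  d <- data.frame(anchor_site = as.character(anchor_site),
                  anchor_allele = as.character(anchor_allele),
                  observed_site = as.character(observed_site),
                  observed_allele = as.character(observed_allele),
                  read_support = as.integer(read_support),
                  stringsAsFactors = FALSE)
  if (any(d$anchor_site == d$observed_site))
    stop("anchor_site must differ from observed_site")
  if (!all(d$anchor_allele %in% c("ref", "alt")) ||
      !all(d$observed_allele %in% c("ref", "alt")))
    stop("alleles must be 'ref' or 'alt'")
  if (any(d$read_support <= 0L)) stop("read_support must be positive")
  d
}

#' Infer cis/trans configuration of two heterozygous sites
#'
#' Observations are grouped by (anchor site, anchor allele). Within each
#' class the majority observed allele carries the class's vote: an anchored
#' allele co-occurring with the partner site's *other* allele supports
#' trans; co-occurring with the *same* category (alt with alt, ref with ref)
#' supports cis. A class whose minority fraction exceeds `noise_fraction`
#' renders the call ambiguous, as do conflicting votes across classes. With
#' only one anchor-allele class present the call is still made but flagged
#' lower-confidence.
#'
#' @param observations data.frame from [amplicon_observations()]
#' @param site_a,site_b the two site identifiers
#' @param noise_fraction tolerated within-class minority fraction
#'   (default 0.05)
#' @return object of class `PhaseCall`: list(configuration, evidence,
#'   low_confidence)
#' @export
infer_phase <- function(observations, site_a, site_b, noise_fraction = 0.05) {
  if (is.null(observations) || nrow(observations) == 0L)
    stop("no amplicon observations supplied")
  obs <- observations
  ok_sites <- (obs$anchor_site == site_a & obs$observed_site == site_b) |
              (obs$anchor_site == site_b & obs$observed_site == site_a)
  if (!all(ok_sites))
    stop("observation anchors a site other than site_a/site_b")
  if (sum(obs$read_support) <= 0L) stop("total read support must be positive")
  key <- paste(obs$anchor_site, obs$anchor_allele, sep = "|")
  votes <- character(); classes <- list()
  for (k in sort(unique(key))) {
    sub <- obs[key == k, , drop = FALSE]
    supp <- tapply(sub$read_support, sub$observed_allele, sum)
    total <- sum(supp)
    maj <- names(supp)[which.max(supp)]
    minority <- (total - max(supp)) / total
    classes[[k]] <- list(anchor = k, majority_observed = maj,
                         minority_fraction = unname(minority))
    if (minority > noise_fraction) {
      return(phase_call("ambiguous", classes,
                        low_confidence = FALSE))
    }
    anchor_allele <- sub$anchor_allele[1]
    votes <- c(votes, if (anchor_allele == maj) "cis" else "trans")
  }
  config <- if (length(unique(votes)) == 1L) votes[1] else "ambiguous"
  anchor_alleles <- unique(obs$anchor_allele)
  phase_call(config, classes,
             low_confidence = length(anchor_alleles) < 2L)
}

phase_call <- function(configuration, evidence, low_confidence) {
  structure(list(configuration = configuration, evidence = evidence,
                 low_confidence = low_confidence), class = "PhaseCall")
}

#' @export
print.PhaseCall <- function(x, ...) {
  cat("PhaseCall:", x$configuration,
      if (x$low_confidence) "(low confidence: single anchor class)" else "",
      "\n")
  invisible(x)
}

#' Simulate allele-specific amplicon observations for a double heterozygote
#'
#' Generates read counts per (anchor site, anchor allele) class consistent
#' with a known cis/trans truth, flipping each read's observed allele with
#' probability `dropout` (allele dropout / mispriming noise).
#'
#' @param truth "cis" or "trans"
#' @param site_a,site_b site identifiers
#' @param reads_per_class reads per anchor class (default 200)
#' @param dropout per-read flip probability (default 0.01)
#' @param anchors which anchor classes to simulate; default both alleles
#'   anchored at `site_b` (wild-type-specific and mutant-specific primers)
#' @return data.frame from [amplicon_observations()]
#' @export
simulate_amplicons <- function(truth = c("trans", "cis"), site_a, site_b,
                               reads_per_class = 200L, dropout = 0.01,
                               anchors = c("ref", "alt")) {
  truth <- match.arg(truth)
  rows <- list()
  for (anchor_allele in anchors) {
    true_obs <- if (truth == "cis") anchor_allele
                else setdiff(c("ref", "alt"), anchor_allele)
    flips <- rbinom(1L, reads_per_class, dropout)
    keep <- reads_per_class - flips
    if (keep > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_site = site_b, anchor_allele = anchor_allele,
        observed_site = site_a, observed_allele = true_obs,
        read_support = keep, stringsAsFactors = FALSE)
    if (flips > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        anchor_site = site_b, anchor_allele = anchor_allele,
        observed_site = site_a,
        observed_allele = setdiff(c("ref", "alt"), true_obs),
        read_support = flips, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  amplicon_observations(d$anchor_site, d$anchor_allele, d$observed_site,
                        d$observed_allele, d$read_support)
}
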