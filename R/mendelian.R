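# Trio transmission-consistency statistics.

# unordered allele pair from a genotype string; NULL when missing
gt_alleles <- function(g) {
  if (is.null(g) || length(g) == 0 || is.na(g) || g %in% c(".", "./.", ".|.")) {
    return(NULL)
  }
  al <- strsplit(g, "[/|]")[[1]]
  if (length(al) != 2 || any(al == ".")) return(NULL)
  sort(al)
}

# one transmitted allele per parent must explain the child
trio_consistent <- function(father, mother, child) {
  for (f in father) {
    for (m in mother) {
      if (identical(sort(c(f, m)), child)) return(TRUE)
    }
  }
  FALSE
}

#' Mendelian consistency of trio genotypes
#'
#' A site is inconsistent when no assignment of one transmitted allele per
#' parent explains the child genotype; sites where any trio member is
#' missing are untested and excluded from the rate denominator.
#'
#' @param sites data.frame with columns `site_id`, `father`, `mother`,
#'   `child` holding genotype strings (`"0/1"`, `"1|1"`, `"./."`, or NA).
#' @return List with `consistent`, `inconsistent`, `untested` counts, the
#'   inconsistency `rate` (NA when no site is testable) and a per-site
#'   `status` vector.
#' @export
mendelian_rate <- function(sites) {
  n <- nrow(sites)
  status <- character(n)
  for (i in seq_len(n)) {
    f <- gt_alleles(sites$father[i])
    m <- gt_alleles(sites$mother[i])
    c0 <- gt_alleles(sites$child[i])
    if (is.null(f) || is.null(m) || is.null(c0)) {
      status[i] <- "untested"
    } else if (trio_consistent(f, m, c0)) {
      status[i] <- "consistent"
    } else {
      status[i] <- "inconsistent"
    }
  }
  ncons <- sum(status == "consistent")
  nincons <- sum(status == "inconsistent")
  list(
    consistent = ncons,
    inconsistent = nincons,
    untested = sum(status == "untested"),
    rate = if (ncons + nincons == 0) NA_real_ else nincons / (ncons + nincons),
    status = setNames(status, if (!is.null(sites$site_id)) sites$site_id else NULL)
  )
}
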