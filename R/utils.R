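#' @importFrom stats rnorm rbinom rbeta rlnorm rgamma runif qnorm pt pchisq
#'   pnorm var mad quantile prcomp lm fisher.test chisq.test p.adjust
#'   smooth.spline predict binomial glm.fit setNames aggregate ave
#'   complete.cases
#' @importFrom utils head write.table packageVersion
NULL

# canonical chromosome ordering: chr1..chr22, chrX, chrY, chrM, then others
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  r <- suppressWarnings(as.numeric(x))
  r[x == "X"] <- 23
  r[x == "Y"] <- 24
  r[x %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26
  r
}

site_order <- function(chrom, pos) order(chrom_rank(chrom), pos)

is_sex_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom)) %in% c("X", "Y")
}

#' Evaluate an expression under a temporary, isolated RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous state, so that internally
#' seeded routines neither consume nor disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  expr
}

# deterministic child seed for a named sub-stream, kept within 32-bit range
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))
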