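# Shared small simulated populations for the unit tests. Sizes are kept
# small so the whole suite stays fast; statistical properties are checked
# on dedicated Monte-Carlo tests with their own configs.

smallConfig <- function(seed = 1L, ...) {
  defaults <- list(
    nFounders = 60L, nGenerations = 3L, litterSize = 2L,
    nChromosomes = 2L, chromLengthBp = 2e7, nSnpsPerChrom = 150L,
    qtlWindows = data.frame(chrom = 1L, startBp = 4e6, endBp = 4.8e6,
                            fraction = 0.05),
    genotypedFraction = 0.5, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# a tiny hand-written trio pedigree: founder sire, founder dam, offspring
trioPedigree <- function() {
  pigPedigree(data.frame(
    id = c("s", "d", "o"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
    sex = c("M", "F", "M"), birthYear = c(2015, 2015, 2016),
    farm = "farm1", stringsAsFactors = FALSE
  ))
}

# full sibs x, y from unrelated parents; w = offspring of the sib mating
fullSibMatingPedigree <- function() {
  pigPedigree(data.frame(
    id = c("s", "d", "x", "y", "w"),
    sire = c(NA, NA, "s", "s", "x"),
    dam = c(NA, NA, "d", "d", "y"),
    sex = c("M", "F", "M", "F", "M"),
    stringsAsFactors = FALSE
  ))
}

# random valid pedigree of n animals for property-style checks
randomPedigree <- function(n, seed = 1L, pFounder = 0.3) {
  set.seed(seed)
  ids <- sprintf("a%04d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 4 && runif(1) > pFounder) {
      males <- which(sex[seq_len(i - 1)] == "M")
      females <- which(sex[seq_len(i - 1)] == "F")
      if (length(males) && length(females)) {
        sire[i] <- ids[males[sample.int(length(males), 1)]]
        dam[i] <- ids[females[sample.int(length(females), 1)]]
      }
    }
  }
  pigPedigree(data.frame(id = ids, sire = sire, dam = dam, sex = sex,
                         stringsAsFactors = FALSE))
}
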