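# Shared fixtures, built in code. Seeds are fixed by convention (42 for
# fixtures) so the suite is deterministic.

trioPed <- function() {
  Pedigree(fid = c(1, 1, 1), id = c("p1", "p2", "c1"),
           father = c(0, 0, "p1"), mother = c(0, 0, "p2"), sex = c(1, 2, 1))
}

# Two founders and k full siblings.
sibPed <- function(k = 2) {
  Pedigree(fid = rep(1, 2 + k),
           id = c("f", "m", paste0("s", seq_len(k))),
           father = c(0, 0, rep("f", k)), mother = c(0, 0, rep("m", k)),
           sex = c(1, 2, rep(1:2, length.out = k)))
}

# Direct lineage of the given depth (founder couple at each step).
lineagePed <- function(depth = 4) {
  fid <- id <- father <- mother <- sex <- character(0)
  add <- function(i, f, m, s) {
    fid <<- c(fid, "1"); id <<- c(id, i); father <<- c(father, f)
    mother <<- c(mother, m); sex <<- c(sex, s)
  }
  add("g1", "0", "0", "1"); add("g1w", "0", "0", "2")
  for (d in 2:depth) {
    add(paste0("g", d), paste0("g", d - 1), paste0("g", d - 1, "w"), "1")
    if (d < depth) add(paste0("g", d, "w"), "0", "0", "2")
  }
  Pedigree(fid = fid, id = id, father = father, mother = mother, sex = sex)
}

# Three generations, 12 members: founder couple, three children (two
# married-in spouses), four grandchildren in two sibships.
threeGenPed <- function() {
  df <- data.frame(
    fid = 1,
    id     = c("f", "m", "a", "b", "c", "aw", "bw", "a1", "a2", "b1", "b2",
               "c0"),
    father = c("0", "0", "f", "f", "f", "0", "0", "a", "a", "bw", "bw", "0"),
    mother = c("0", "0", "m", "m", "m", "0", "0", "aw", "aw", "b", "b", "0"),
    sex    = c(1, 2, 1, 2, 2, 2, 1, 1, 2, 1, 2, 1))
  Pedigree(df)
}

# First-cousin pedigree: two sibs marry out, their children are cousins.
cousinPed <- function() {
  df <- data.frame(
    fid = 1,
    id     = c("f", "m", "a", "b", "aw", "bw", "a1", "b1"),
    father = c("0", "0", "f", "f", "0", "0", "a", "bw"),
    mother = c("0", "0", "m", "m", "0", "0", "aw", "b"),
    sex    = c(1, 2, 1, 2, 2, 1, 1, 2))
  Pedigree(df)
}

# One shared default-condition study, simulated once per test run.
.fixtureCache <- new.env(parent = emptyenv())

sharedPed <- function() {
  if (is.null(.fixtureCache$ped))
    .fixtureCache$ped <- simulatePedigrees(simConfig(), seed = 42)
  .fixtureCache$ped
}

sharedKin <- function() {
  if (is.null(.fixtureCache$kin))
    .fixtureCache$kin <- kinshipMatrix(sharedPed())
  .fixtureCache$kin
}

sharedStudy <- function() {
  if (is.null(.fixtureCache$study))
    .fixtureCache$study <- simulateStudy(simConfig(nSNPs = 400), seed = 42,
                                         ped = sharedPed(), kin = sharedKin())
  .fixtureCache$study
}

# Null study: no planted causal variants.
sharedNullStudy <- function() {
  if (is.null(.fixtureCache$null))
    .fixtureCache$null <- simulateStudy(
      simConfig(nSNPs = 500, plantDichotomous = list(),
                plantQuantitative = list()),
      seed = 42, ped = sharedPed(), kin = sharedKin())
  .fixtureCache$null
}
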