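# Small hand-sized fixtures used across the suite.

# profiles + state realizing given phosphorylated-Ft and unphosphorylated-Ds
# vectors (totals: ft = 1, ds chosen so that dsU = dsTotal - dsP holds)
stateFromFtpDsu <- function(ftP, dsU, dsTotal = rep(1.5, length(ftP))) {
    stopifnot(all(dsU <= dsTotal), all(ftP <= 1))
    list(profiles = expressionProfiles(
             fj = rep(0.5, length(ftP)),
             dsTotal = dsTotal,
             ftTotal = rep(1, length(ftP))),
         state = phosphoState(ftP = ftP, dsP = dsTotal - dsU))
}

# random valid state on given profiles (test-local RNG, not the package's)
randomState <- function(profiles, seed) {
    set.seed(seed)
    n <- nCells(profiles)
    phosphoState(ftP = runif(n) * ftTotal(profiles),
                 dsP = runif(n) * dsTotal(profiles))
}

wtConfig <- function() defaultWildtypeConfig()
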