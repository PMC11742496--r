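# Reference fatty-acid compositions built in code (control F/2 vs optimized
# medium), plus an independent double-bond lookup used as the ADU oracle.

control_acids <- c("C14:0" = 7.25, "C16:0" = 24.94,
                   "C16:1t" = 26.77, "C18:1t" = 1.80, "C24:1" = 3.52,
                   "C18:2(n-6)" = 2.68, "C18:3(n-6)" = 1.96, "C20:5n3" = 7.04)

optimized_acids <- c("C14:0" = 6.27, "C16:0" = 39.84, "C18:0" = 1.22,
                     "C20:0" = 1.39, "C16:1t" = 14.04, "C18:1(n-9)" = 6.55,
                     "C18:2(n-6)" = 4.76, "C18:3(n-6)" = 3.38,
                     "C20:5n3" = 4.80, "C20:3n3" = 0.82, "C18:3n3" = 0.93)

make_control_profile <- function() {
  fa_profile("control", "control F/2", names(control_acids),
             unname(control_acids),
             reported_class_totals = c(sfa = 32.19, mufa = 36.12, pufa = 11.68))
}

make_optimized_profile <- function() {
  fa_profile("optimized", "optimized medium", names(optimized_acids),
             unname(optimized_acids),
             reported_class_totals = c(sfa = 48.72, mufa = 20.59, pufa = 14.71))
}

# Independent of the parser: double-bond counts keyed by shorthand.
db_lookup <- c("C14:0" = 0, "C16:0" = 0, "C18:0" = 0, "C20:0" = 0,
               "C16:1t" = 1, "C17:1" = 1, "C18:1t" = 1, "C24:1" = 1,
               "C18:1(n-9)" = 1, "C18:2(n-6)" = 2, "C18:3(n-6)" = 3,
               "C20:5n3" = 5, "C20:3n3" = 3, "C18:3n3" = 3)

# Oracle ADU: plain weighted sum from the lookup, never touching the parser.
oracle_adu <- function(acids) sum(db_lookup[names(acids)] * acids) / 100

# Random valid profile for property-style tests.
random_profile <- function(n_total = 90) {
  pool <- names(db_lookup)
  k <- sample(3:length(pool), 1)
  acids <- sample(pool, k)
  w <- stats::runif(k)
  pct <- w / sum(w) * n_total
  fa_profile("fuzz", "fuzz", acids, pct)
}
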