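# a 10-record fixture with one constructed violation per rule, boundary
# values, a missing-annotation record and a double violation
filter_fixture <- function() {
  geno <- matrix(0L, nrow = 10, ncol = 2,
                 dimnames = list(NULL, c("S1", "S2")))
  variant_set(data.frame(
    chrom = "1",
    pos = as.integer(1:10 * 100),
    id = ".",
    ref = "A", alt = "G",
    #      1    2     3     4    5     6    7    8    9    10
    qd  = c(1.9, 2.0,  25,   25,  25,   25,  NA,  1.0, 25,  25),
    mq  = c(60,  60,   39.9, 60,  60,   60,  NA,  30,  60,  60),
    fs  = c(5,   5,    5,    60.5, 60,  5,   NA,  5,   5,   5),
    mqranksum      = c(0, 0, 0, 0, 0, -12.6, NA, 0, 0, 0),
    readposranksum = c(0, 0, 0, 0, 0, 0,     NA, 0, -8.5, 0),
    stringsAsFactors = FALSE
  ), geno)
}
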