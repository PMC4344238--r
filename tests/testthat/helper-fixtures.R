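## shared fixtures, built once per test run

uniform_bg <- function() {
  structure(list(order = 0,
                 trans = matrix(0.25, 1, 4,
                                dimnames = list("", c("A", "C", "G", "T"))),
                 stationary = setNames(rep(0.25, 4), c("A", "C", "G", "T"))),
            class = "dna_background")
}

.fix <- new.env()

## order-3 chain, trained background and discovery calibration shared by the
## motif tests (seeded once)
motif_fixture <- function() {
  if (is.null(.fix$motif)) {
    set.seed(401)
    chain <- trninfer:::random_background_chain(3)
    bgseqs <- sample_background(chain, rep(150, 40))
    bg <- train_background(bgseqs, order = 3)
    pool <- trninfer:::build_null_pool(bg, 300, 200)
    cal <- discovery_calibration(bg, lengths = rep(c(100, 150, 200), 4),
                                 n_seqs = 4:8, n_cal = 80, null_pool = pool)
    .fix$motif <- list(chain = chain, bg = bg, pool = pool, cal = cal)
  }
  .fix$motif
}

mk_bg_seqs <- function(chain, n, L) sample_background(chain, rep(L, n))

## small synthetic dataset + pipeline fit shared by pipeline-level tests
small_fit_fixture <- function() {
  if (is.null(.fix$small)) {
    sc <- trn_scenario("easy", n_ortholog_groups = 60, n_tfs = 4, seed = 11)
    d <- simulate_trn_data(sc)
    fit <- infer_trn(d)
    .fix$small <- list(data = d, fit = fit)
  }
  .fix$small
}

## tiny gene table on one replicon: genes at given starts, length 100
toy_genes <- function(starts, strands = rep("+", length(starts)),
                      replicon = "chr", genome = "g1", len = 100) {
  load_annotations(data.frame(
    gene_id = sprintf("gene%02d", seq_along(starts)),
    replicon_id = replicon, start = starts, end = starts + len - 1,
    strand = strands), genome_id = genome)
}

random_dna <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
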