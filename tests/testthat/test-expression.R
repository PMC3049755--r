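mkSamples <- function(n_tis, n_rep) data.frame(
    sample_id = paste0(rep(sprintf("t%02d", 1:n_tis), each = n_rep), "_r",
                       rep(1:n_rep, n_tis)),
    tissue = rep(sprintf("t%02d", 1:n_tis), each = n_rep),
    replicate = rep(1:n_rep, n_tis), stringsAsFactors = FALSE)

test_that("presence collapses by OR over replicates", {
    s <- mkSamples(3, 3)
    calls <- matrix(FALSE, 2, 9, dimnames = list(c("g1", "g2"),
                                                 s$sample_id))
    calls["g1", c("t01_r2", "t02_r1")] <- TRUE   # 1 of 3 replicates
    cc <- collapseCalls(calls, s)
    expect_equal(unname(cc$breadth), c(2, 0))
    # idempotent and replicate-order invariant
    s2 <- s[sample(nrow(s)), ]
    cc2 <- collapseCalls(calls[, s2$sample_id], s2)
    expect_equal(cc$breadth, cc2$breadth)
    expect_equal(cc$presence["g1", cc$presence["g1", ] |> which() |> names()],
                 cc2$presence["g1", c("t01", "t02")])
})

test_that("breadth comparison reports shares at each threshold", {
    breadth <- c(0, 2, 4, 60)
    lsg <- c(TRUE, TRUE, TRUE, FALSE)
    out <- breadthComparison(breadth, lsg, low_breadth_at = c(0, 4))
    expect_equal(out$low_breadth$share_pct[
        out$low_breadth$group == "LSG" & out$low_breadth$b == 4], 100)
    expect_equal(out$low_breadth$share_pct[
        out$low_breadth$group == "nonLSG" & out$low_breadth$b == 4], 0)
    # every gene at breadth 0: all shares 100
    all0 <- breadthComparison(rep(0, 6), rep(c(TRUE, FALSE), 3))
    expect_true(all(all0$low_breadth$share_pct == 100))
    # printed-share style: 52.72% of a fixture cohort at four or fewer
    expect_equal(pctShare(sum(c(rep(4, 5272), rep(10, 4728)) <= 4), 10000),
                 52.72)
})

test_that("per-tissue expression medians are group-restricted to present genes", {
    s <- mkSamples(2, 2)
    expr <- matrix(rep(c(2.0, 2.4251, 3.0, 7.0), 4), 4, 4,
                   dimnames = list(paste0("g", 1:4), s$sample_id))
    presence <- matrix(TRUE, 4, 2,
                       dimnames = list(paste0("g", 1:4),
                                       c("t01", "t02")))
    lsg <- c(TRUE, TRUE, TRUE, FALSE)
    out <- expressionDistributions(expr, s, presence, lsg)
    expect_equal(out$median_expression[out$group == "LSG" &
                                       out$tissue == "t01"], 2.4251)
    # symmetric groups give identical medians
    out2 <- expressionDistributions(expr, s, presence,
                                    c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(out2$n_present[out2$tissue == "t01"], c(2, 2))
    # absent genes are excluded
    presence[, "t02"] <- FALSE
    out3 <- expressionDistributions(expr, s, presence, lsg)
    expect_true(is.na(out3$median_expression[out3$tissue == "t02" &
                                             out3$group == "LSG"]))
})

test_that("DE thresholds apply to adjusted p and |log2 fold change|", {
    tb <- data.frame(gene_id = c("a", "b", "c", "d"),
                     log2fc = c(0.60, 0, -0.9, 0.60),
                     adj_p = c(0.005, 0.001, 0.003, 0.02),
                     stringsAsFactors = FALSE)
    de <- callDe(tb)
    expect_equal(de$up, "a")           # 0.60 > log2(1.5) = 0.585
    expect_equal(de$down, "c")
    expect_equal(intersect(de$up, de$down), character())
    expect_error(callDe(data.frame(gene_id = "a", log2fc = 1)),
                 "adj_p")
})

test_that("raw-mode DE reproduces an independent BH computation", {
    set.seed(51)
    n <- 20
    treat <- matrix(rnorm(n * 3), n, 3,
                    dimnames = list(sprintf("g%02d", 1:n), NULL))
    treat[1:3, ] <- treat[1:3, ] + 3
    ctrl <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(sprintf("g%02d", 1:n), NULL))
    de <- callDe(treatment = treat, control = ctrl)
    p <- vapply(1:n, function(i) t.test(treat[i, ], ctrl[i, ])$p.value,
                numeric(1))
    # independent sort-and-cummin BH oracle
    o <- order(p)
    adj <- numeric(n)
    adj[o[n:1]] <- cummin((p[o] * n / seq_len(n))[n:1])
    adj <- pmin(adj, 1)
    expect_equal(de$table$adj_p, adj, tolerance = 1e-12)
})

test_that("LSG stress enrichment flags excess and respects the null", {
    lsg <- sprintf("L%02d", 1:50)
    uni <- c(lsg, sprintf("N%03d", 1:950))
    de <- list(ct1 = list(up = c(lsg[1:20], sprintf("N%03d", 1:80)),
                          down = character()))
    out <- lsgStressEnrichment(de, uni, lsg)
    expect_true(out$enriched[out$direction == "up"])
    expect_equal(out$k[out$direction == "up"], 20)
    expect_equal(out$p_value[out$direction == "down"], 1)  # k = 0
    expect_error(lsgStressEnrichment(
        list(ct = list(up = uni, down = character())), uni[1:5], lsg),
        "larger than")
    ov <- attr(out, "lsg_de_overlap")
    expect_equal(unname(ov["up"]), 20)
})

test_that("planted breadth and expression shift are recovered", {
    labels <- data.frame(gene_id = sprintf("g%03d", 1:500),
                         class = rep(c("lsg_like", "conserved_like"),
                                     c(150, 350)), stringsAsFactors = FALSE)
    pars <- c(n_tissues = 63, n_replicates = 3, lsg_breadth_mean = 4,
              nonlsg_breadth_mean = 51, lsg_expr_shift = -1.5,
              n_stress_contrasts = 1, planted_enrichment_odds = 1)
    ex <- generateExpression(labels, pars, seed = 5L)
    expect_true(all(is.finite(ex$expr)))
    expect_true(is.logical(ex$calls))
    cc <- collapseCalls(ex$calls, ex$samples)
    is_lsg <- labels$class == "lsg_like"
    expect_lt(abs(median(cc$breadth[is_lsg]) - 4), 0.25 * 4)
    expect_lt(abs(median(cc$breadth[!is_lsg]) - 51), 0.25 * 51)
    # a planted -0.4 log2 shift is recovered within 0.1 when presence is
    # plentiful
    pars2 <- c(n_tissues = 12, n_replicates = 3, lsg_breadth_mean = 10,
               nonlsg_breadth_mean = 10, lsg_expr_shift = -0.4,
               n_stress_contrasts = 1, planted_enrichment_odds = 1)
    ex2 <- generateExpression(labels, pars2, seed = 6L)
    cc2 <- collapseCalls(ex2$calls, ex2$samples)
    d <- expressionDistributions(ex2$expr, ex2$samples, cc2$presence,
                                 is_lsg)
    gap <- with(d, median_expression[group == "LSG"] -
                   median_expression[group == "nonLSG"])
    expect_lt(abs(mean(gap, na.rm = TRUE) + 0.4), 0.1)
    expect_error(generateExpression(labels,
                                    replace(pars, "n_replicates", 1), 1L),
                 "replicates")
})
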