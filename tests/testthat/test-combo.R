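test_that("reference-line assignment maximizes Pearson correlation", {
    set.seed(30)
    panel <- matrix(rexp(300 * 4), 300, 4,
                    dimnames = list(sprintf("G%03d", 1:300),
                                    c("A375", "HT29", "MCF7", "PC3")))
    self <- assignReferenceLine(setNames(panel[, "MCF7"], rownames(panel)),
                                panel)
    expect_equal(self$line, "MCF7")
    expect_equal(self$correlation, 1, tolerance = 1e-12)

    ## noisy copies assign correctly
    for (ln in colnames(panel)) {
        q <- panel[, ln] + rnorm(300, 0, 0.05)
        names(q) <- rownames(panel)
        expect_equal(assignReferenceLine(q, panel)$line, ln)
    }
    ## exact tie -> first column in stored order
    tied <- cbind(first = panel[, 1], second = panel[, 1])
    expect_equal(assignReferenceLine(
        setNames(panel[, 1], rownames(panel)), tied)$line, "first")
    expect_error(assignReferenceLine(c(x = 1), panel), "shared genes")
})

test_that("deconvolution recovers exact mixtures and returns simplex
           weights", {
    set.seed(31)
    sig <- matrix(rexp(120 * 3, 0.2), 120, 3,
                  dimnames = list(sprintf("G%03d", 1:120), c("s0", "s1", "s2")))
    w <- c(0.2, 0.3, 0.5)
    meta <- data.frame(experiment_id = c("e1", "e2", "ctrl"),
                       compound = c("a", "b", "control"),
                       concentration = c(1, 1, 0), unit = "uM",
                       is_control = c(FALSE, FALSE, TRUE))
    gep <- cbind(sig %*% w, sig[, 2], sig %*% c(1, 1, 1) / 3)
    dimnames(gep) <- list(rownames(sig), c("e1", "e2", "ctrl"))
    screen <- PerturbationScreen(gep, meta)
    props <- deconvolve(screen, sig)
    expect_equal(unname(props["e1", ]), w, tolerance = 1e-6)
    expect_equal(unname(props["e2", ]), c(0, 1, 0), tolerance = 1e-9)
    expect_true(all(props >= 0))
    expect_equal(unname(rowSums(props)), rep(1, 3), tolerance = 1e-9)

    expect_warning(deconvolve(screen, cbind(sig[, 1], sig[, 1])),
                   "rank-deficient")
})

test_that("noisy deconvolution keeps mean absolute proportion error small", {
    set.seed(32)
    sig <- matrix(rexp(200 * 4, 0.2), 200, 4,
                  dimnames = list(sprintf("G%03d", 1:200), paste0("s", 0:3)))
    err <- c()
    for (i in 1:10) {
        w <- runif(4); w <- w / sum(w)
        y <- as.vector(sig %*% w)
        y <- pmax(y + rnorm(200, 0, 0.05 * mean(y)), 0)
        meta <- data.frame(experiment_id = c("e", "c"),
                           compound = c("a", "control"),
                           concentration = c(1, 0), unit = "uM",
                           is_control = c(FALSE, TRUE))
        gep <- cbind(e = y, c = as.vector(sig %*% w))
        rownames(gep) <- rownames(sig)
        screen <- PerturbationScreen(gep, meta)
        props <- deconvolve(screen, sig)
        err <- c(err, mean(abs(props["e", ] - w)))
    }
    expect_lt(mean(err), 0.05)
})

test_that("kill calling applies the 90% rule with dose consistency", {
    ## hand-built proportions: control 0.20 -> treated 0.01 is a kill
    sig <- diag(3) + 0.1
    rownames(sig) <- paste0("G", 1:3); colnames(sig) <- paste0("s", 0:2)
    meta <- data.frame(
        experiment_id = c("ctrl", "lo", "hi"),
        compound = c("control", "dx", "dx"),
        concentration = c(0, 1, 10), unit = "uM",
        is_control = c(TRUE, FALSE, FALSE))
    screen <- PerturbationScreen(matrix(1, 3, 3,
        dimnames = list(rownames(sig), meta$experiment_id)), meta)
    props <- rbind(ctrl = c(0.20, 0.40, 0.40),
                   lo = c(0.01, 0.50, 0.49),
                   hi = c(0.02, 0.49, 0.49))
    colnames(props) <- colnames(sig)
    kt <- callKilled(props, screen)
    lo0 <- kt[kt$experiment_id == "lo" & kt$subpopulation == "s0", ]
    expect_equal(lo0$reduction, 1 - 0.01 / 0.20)
    expect_true(lo0$killed)

    ## reduction 0.95 at low dose but only 0.60 at the higher dose: vetoed
    props["hi", "s0"] <- 0.20 * 0.40  # hi-dose reduction = 0.60
    kt <- callKilled(props, screen)
    lo0 <- kt[kt$experiment_id == "lo" & kt$subpopulation == "s0", ]
    expect_true(lo0$candidate)
    expect_false(lo0$killed)

    ## zero-control subpopulation excluded with a warning
    props0 <- props; props0[, "s2"] <- c(0, 0.5, 0.5)
    expect_warning(kt0 <- callKilled(props0, screen), "zero control")
    expect_false("s2" %in% kt0$subpopulation)
})

test_that("randomized kill tables match a brute-force rule application", {
    set.seed(34)
    for (rep in 1:5) {
        nSub <- 4
        doses <- c(1, 5, 25)
        meta <- data.frame(
            experiment_id = c("ctrl", paste0("a", 1:3), paste0("b", 1:3)),
            compound = c("control", rep("a", 3), rep("b", 3)),
            concentration = c(0, doses, doses), unit = "uM",
            is_control = c(TRUE, rep(FALSE, 6)))
        props <- matrix(runif(7 * nSub, 0.001, 1), 7, nSub)
        props <- props / rowSums(props)
        dimnames(props) <- list(meta$experiment_id, paste0("s", 1:nSub))
        screen <- PerturbationScreen(matrix(1, 2, 7,
            dimnames = list(c("G1", "G2"), meta$experiment_id)), meta)
        ## inject some strong kills so the rule paths are exercised
        props[2:4, 1] <- props["ctrl", 1] * c(0.02, 0.03, 0.05)
        props[5, 2] <- props["ctrl", 2] * 0.04
        props[6, 2] <- props["ctrl", 2] * 0.50   # inconsistent higher dose
        kt <- callKilled(props, screen, 0.90, 0.75)
        for (r in seq_len(nrow(kt))) {
            red <- 1 - props[kt$experiment_id[r], kt$subpopulation[r]] /
                props["ctrl", kt$subpopulation[r]]
            expect_equal(kt$reduction[r], red, tolerance = 1e-12)
            cand <- red > 0.90
            expect_equal(kt$candidate[r], cand)
            if (cand) {
                same <- meta$compound == kt$compound[r] & !meta$is_control &
                    meta$concentration > kt$concentration[r]
                ok <- TRUE
                for (id in meta$experiment_id[same]) {
                    redH <- 1 - props[id, kt$subpopulation[r]] /
                        props["ctrl", kt$subpopulation[r]]
                    if (redH < 0.75) ok <- FALSE
                }
                expect_equal(kt$killed[r], ok)
            } else expect_false(kt$killed[r])
        }
    }
})

## Minimal kill table builder for greedy-search tests: one experiment per
## compound, given kill sets and per-subpopulation reductions.
makeKillTable <- function(killSets, reductions, subpops) {
    rows <- list()
    for (id in names(killSets)) {
        for (s in subpops) {
            rows[[length(rows) + 1L]] <- data.frame(
                experiment_id = id, compound = id, concentration = 1,
                unit = "uM", subpopulation = s,
                reduction = reductions[[id]][s],
                candidate = s %in% killSets[[id]],
                killed = s %in% killSets[[id]])
        }
    }
    kt <- do.call(rbind, rows)
    class(kt) <- c("KillTable", "data.frame")
    kt
}

test_that("greedy combination search follows count-then-efficacy and
           branches on exact ties", {
    subpops <- paste0("s", 1:3)
    ## A kills {1,2}; B kills {3}; C kills {2,3}; C's total reduction beats B
    red <- list(A = c(s1 = 0.95, s2 = 0.96, s3 = 0.10),
                B = c(s1 = 0.00, s2 = 0.05, s3 = 0.93),
                C = c(s1 = 0.05, s2 = 0.95, s3 = 0.94))
    kt <- makeKillTable(list(A = c("s1", "s2"), B = "s3", C = c("s2", "s3")),
                        red, subpops)
    plans <- greedyCombination(kt)
    expect_length(plans, 1)
    expect_equal(plans[[1]]$steps$experiment_id, c("A", "C"))
    expect_setequal(plans[[1]]$killed, subpops)
    expect_equal(plans[[1]]$steps$newly_killed[[2]], "s3")

    ## exhaustive check: no ordering of single perturbations kills more in
    ## step one than the greedy choice
    singles <- sapply(list(c("s1", "s2"), "s3", c("s2", "s3")), length)
    expect_equal(length(plans[[1]]$steps$newly_killed[[1]]), max(singles))

    ## one perturbation kills everything -> single step
    ktAll <- makeKillTable(list(Z = subpops, B = "s3"),
                           list(Z = c(s1 = .95, s2 = .95, s3 = .95),
                                B = c(s1 = 0, s2 = 0, s3 = .93)), subpops)
    plansAll <- greedyCombination(ktAll)
    expect_equal(nrow(plansAll[[1]]$steps), 1)

    ## identical kill sets and efficacy -> two branched plans
    ktTie <- makeKillTable(list(P = "s1", Q = "s1"),
                           list(P = c(s1 = .95, s2 = 0, s3 = 0),
                                Q = c(s1 = .95, s2 = 0, s3 = 0)), subpops)
    plansTie <- greedyCombination(ktTie)
    expect_length(plansTie, 2)
    expect_setequal(vapply(plansTie, function(p)
        p$steps$experiment_id[1], character(1)), c("P", "Q"))

    ## nothing killed -> empty plan list with a message
    ktNone <- makeKillTable(list(P = character(0)),
                            list(P = c(s1 = .1, s2 = .1, s3 = .1)), subpops)
    expect_message(plansNone <- greedyCombination(ktNone), "no perturbation")
    expect_length(plansNone, 0)
})

test_that("greedy plans are consistent and optimal on disjoint kill sets", {
    set.seed(35)
    subpops <- paste0("s", 1:6)
    killSets <- list(d1 = c("s1", "s2"), d2 = c("s3"), d3 = c("s4", "s5"),
                     d4 = c("s6"), d5 = character(0))
    red <- lapply(killSets, function(ks)
        setNames(ifelse(subpops %in% ks, 0.95, runif(6, 0, 0.3)), subpops))
    kt <- makeKillTable(killSets, red, subpops)
    plans <- greedyCombination(kt)
    for (p in plans) {
        newly <- p$steps$newly_killed
        expect_true(all(lengths(newly) > 0))
        expect_equal(sort(unique(unlist(newly))), sort(p$killed))
        expect_false(any(duplicated(unlist(newly))))
    }
    ## exhaustive search over all orderings of all subsets
    ids <- names(killSets)
    bestCoverage <- 0
    for (k in 1:5) {
        combs <- combn(ids, k, simplify = FALSE)
        for (cb in combs)
            bestCoverage <- max(bestCoverage,
                                length(unique(unlist(killSets[cb]))))
    }
    expect_equal(length(plans[[1]]$killed), bestCoverage)
})
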