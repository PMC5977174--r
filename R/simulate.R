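## Synthetic data generation emulating the six-species study design:
## codon alignments on the dioecious/non-dioecious tree, gene-class
## metadata, diploid polymorphism panels under sex-specific ploidy, and
## sexed expression matrices. Every simulator is deterministic given its
## seed; generated truth is written next to the data and never read by the
## analysis stages.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

# Stable 31-bit hash of a string, mixed with the master seed: used to spawn
# order-independent per-gene child seeds.
child_seed <- function(master, id) {
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

#' The six-taxon study tree
#'
#' A fixed topology with a three-species dioecious clade
#' (`S_latifolia`, `S_dioica`, `S_diclinis`) and three non-dioecious
#' outgroup species. Branch lengths are in expected substitutions per codon
#' site; tip and internal branches use two round values so transition
#' matrices are shared across branches.
#'
#' @param tip_len,internal_len branch lengths (defaults 0.05 / 0.025).
#' @return an [ape::phylo] tree.
#' @export
silene_species_tree <- function(tip_len = 0.05, internal_len = 0.025) {
  tr <- ape::read.tree(text = paste0(
    "(((S_latifolia,S_dioica),S_diclinis),(S_vulgaris,(S_gallica,",
    "S_acaulis)));"))
  ntip <- length(tr$tip.label)
  tr$edge.length <- ifelse(tr$edge[, 2] <= ntip, tip_len, internal_len)
  tr
}

#' Taxa of the dioecious foreground clade
#' @export
dioecious_taxa <- function() c("S_latifolia", "S_dioica", "S_diclinis")

#' Simulate a codon alignment on a tree
#'
#' Evolves codon states branch by branch using transition probabilities from
#' the model's rate matrices. Site classes are drawn from `classes`
#' (probability plus background/foreground omega per class); foreground
#' branches, when declared, use the class's foreground omega.
#'
#' @param tree an [ape::phylo] with branch lengths (substitutions/codon).
#' @param L number of codon sites.
#' @param kappa transition/transversion ratio.
#' @param omega shortcut for a single-class model (ignored when `classes`
#'   given).
#' @param classes optional data.frame with columns `prob`, `w_bg`, `w_fg`.
#' @param foreground_taxa tips whose clade uses the foreground omegas.
#' @param freqs codon equilibrium frequencies (default equal).
#' @param seed integer seed; same seed, same alignment.
#' @return a `codon_alignment` with attribute `site_class`.
#' @export
simulate_codon_alignment <- function(tree, L, kappa = 2, omega = 0.2,
                                     classes = NULL, foreground_taxa = NULL,
                                     freqs = NULL, seed = 1) {
  if (is.null(freqs)) freqs <- rep(1 / 61, 61)
  if (is.null(classes))
    classes <- data.frame(prob = 1, w_bg = omega, w_fg = omega)
  if (abs(sum(classes$prob) - 1) > 1e-8)
    stop("class probabilities must sum to 1")
  tr <- ape::reorder.phylo(tree, "postorder")
  fg <- if (is.null(foreground_taxa)) rep(0L, nrow(tr$edge)) else
    label_foreground(tr, foreground_taxa)
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  with_seed(seed, {
    cls <- sample.int(nrow(classes), L, replace = TRUE, prob = classes$prob)
    omegas <- unique(c(classes$w_bg, classes$w_fg))
    eigs <- lapply(omegas, function(w)
      rev_eigen(codon_rate_matrix(kappa, w, freqs), freqs))
    states <- matrix(NA_integer_, ntip + tr$Nnode, L)
    states[root, ] <- sample.int(61, L, replace = TRUE, prob = freqs)
    Pcache <- new.env(parent = emptyenv())
    for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder
      par_n <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      w_here <- if (fg[e] == 1L) classes$w_fg[cls] else classes$w_bg[cls]
      child <- integer(L)
      for (wi in unique(w_here)) {
        key <- paste0(match(wi, omegas), "_", tr$edge.length[e])
        P <- Pcache[[key]]
        if (is.null(P)) {
          P <- prob_matrix(eigs[[match(wi, omegas)]], tr$edge.length[e])
          P <- P / rowSums(P)
          Pcache[[key]] <- P
        }
        sel <- which(w_here == wi)
        for (s in unique(states[par_n, sel])) {
          at <- sel[states[par_n, sel] == s]
          child[at] <- sample.int(61, length(at), replace = TRUE,
                                  prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    gcd <- genetic_code()
    seqs <- vapply(seq_len(ntip), function(i)
      paste(gcd$codons[states[i, ]], collapse = ""), "")
    names(seqs) <- tr$tip.label
    al <- codon_alignment(seqs)
    attr(al, "site_class") <- cls
    al
  })
}

#' Configuration for a synthetic gene set
#'
#' Defaults emulate the study design: ~18% of genes X-linked with ~80% of
#' the X class non-hemizygous, a dioecious foreground clade of three taxa,
#' a foreground omega shift up for non-hemizygous X genes and down for
#' hemizygous X genes, and female-biased expression enriched on the X.
#'
#' @param n_autosomal,n_x_nonhemizygous,n_x_hemizygous,n_par gene counts per
#'   linkage class.
#' @param L codon sites per gene.
#' @param kappa transition/transversion ratio.
#' @param omega0_meanlog,omega0_sdlog log-normal law for each gene's
#'   background omega.
#' @param fg_multiplier named multipliers applied to the background omega on
#'   foreground branches, per class.
#' @param female_biased_fraction named per-class probability that a gene is
#'   female-biased.
#' @param tree species tree (default [silene_species_tree()]).
#' @param foreground_taxa the dioecious clade.
#' @param theta silent-site polymorphism theta for companion panels.
#' @param n_males,n_females breeding population sizes for the coalescent.
#' @param n_individuals diploid individuals sampled per panel.
#' @param seed master seed; per-gene child seeds are spawned by stable
#'   hashing of gene ids.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_autosomal = 45, n_x_nonhemizygous = 8,
                              n_x_hemizygous = 2, n_par = 1, L = 300,
                              kappa = 2, omega0_meanlog = log(0.15),
                              omega0_sdlog = 0.5,
                              fg_multiplier = c(autosomal = 1,
                                                x_nonhemizygous = 2,
                                                x_hemizygous = 0.5,
                                                par = 1),
                              female_biased_fraction = c(autosomal = 0.15,
                                                         x_nonhemizygous = 0.41,
                                                         x_hemizygous = 0.41,
                                                         par = 0.15),
                              tree = silene_species_tree(),
                              foreground_taxa = dioecious_taxa(),
                              theta = 0.01, n_males = 500, n_females = 500,
                              n_individuals = 5, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_autosomal >= 0, n_x_nonhemizygous >= 0, n_x_hemizygous >= 0,
            n_par >= 0, theta > 0)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a gene set with metadata
#'
#' Writes one FASTA per gene plus a metadata table carrying the linkage
#' class, hemizygosity, female-bias flag and the true generating parameters
#' (for recovery checks; the analysis never reads the truth columns).
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, FASTAs, the species tree,
#'   `metadata.tsv` and a JSON-ish config echo are written there.
#' @return metadata data.frame (invisibly when writing).
#' @export
simulate_gene_set <- function(config, out_dir = NULL) {
  classes <- c(rep("autosomal", config$n_autosomal),
               rep("x_nonhemizygous", config$n_x_nonhemizygous),
               rep("x_hemizygous", config$n_x_hemizygous),
               rep("par", config$n_par))
  ids <- sprintf("gene%04d", seq_along(classes))
  meta <- data.frame(gene = ids, class = classes,
                     linkage = ifelse(classes == "autosomal", "autosomal",
                                      ifelse(classes == "par", "PAR", "X")),
                     hemizygous = classes == "x_hemizygous",
                     stringsAsFactors = FALSE)
  n <- nrow(meta)
  meta$female_biased <- vapply(seq_len(n), function(i) with_seed(
    child_seed(config$seed, paste0(ids[i], "_bias")),
    stats::runif(1) < config$female_biased_fraction[[meta$class[i]]]),
    logical(1))
  meta$true_omega_back <- vapply(seq_len(n), function(i) with_seed(
    child_seed(config$seed, paste0(ids[i], "_w")),
    stats::rlnorm(1, config$omega0_meanlog, config$omega0_sdlog)),
    numeric(1))
  meta$true_omega_fore <- meta$true_omega_back *
    config$fg_multiplier[meta$class]
  meta$true_kappa <- config$kappa
  aligns <- vector("list", n)
  for (i in seq_len(n)) {
    aligns[[i]] <- simulate_codon_alignment(
      config$tree, config$L, kappa = config$kappa,
      classes = data.frame(prob = 1, w_bg = meta$true_omega_back[i],
                           w_fg = meta$true_omega_fore[i]),
      foreground_taxa = config$foreground_taxa,
      seed = child_seed(config$seed, ids[i]))
  }
  meta$path <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      p <- file.path(out_dir, paste0(ids[i], ".fasta"))
      write_codon_fasta(aligns[[i]], p)
      meta$path[i] <- p
    }
    ape::write.tree(config$tree, file.path(out_dir, "species_tree.nwk"))
    write.table(meta, file.path(out_dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    echo <- config[!vapply(config, is.object, logical(1))]
    echo$tree <- ape::write.tree(config$tree)
    writeLines(paste0("{", paste(sprintf('"%s": "%s"', names(echo),
      vapply(echo, function(v) paste(format(v), collapse = ","), "")),
      collapse = ", "), "}"), file.path(out_dir, "config.json"))
    return(invisible(structure(meta, alignments = aligns)))
  }
  structure(meta, alignments = aligns)
}

## ---- polymorphism panels under sex-specific ploidy -------------------

# Per-generation pair-coalescence probability derived from the mode's copy
# counts and transmission rules (never from a hard-coded X/A ratio): a
# lineage's parent sex follows the stationary law of the holder-sex chain,
# and two lineages coalesce when they pick the same parent copy.
pair_coal_prob <- function(mode, n_males, n_females) {
  copies <- switch(mode, autosome = c(male = 2, female = 2),
                   X = c(male = 1, female = 2),
                   stop("mode must be 'X' or 'autosome'"))
  # P(parent male | holder sex): autosomal copies come from either parent;
  # an X in a male is maternal, an X in a female is paternal or maternal.
  p_parent_male <- if (mode == "autosome") c(male = 0.5, female = 0.5) else
    c(male = 0, female = 0.5)
  # stationary holder-sex distribution of the backwards chain
  A <- rbind(c(p_parent_male[["male"]] - 1, p_parent_male[["female"]]),
             c(1, 1))
  q <- solve(A, c(0, 1))  # (q_male, q_female)
  beta_m <- q[1]
  beta_f <- 1 - beta_m
  beta_m^2 / (n_males * copies[["male"]]) +
    beta_f^2 / (n_females * copies[["female"]])
}

#' Simulate a diploid polymorphism panel under sex-specific ploidy
#'
#' Neutral coalescent for one gene: lineage bookkeeping follows the mode's
#' copy counts (autosome: two copies in every individual; X: two in females,
#' one in males), genealogy times are exponential with the per-generation
#' pair-coalescence probability implied by those counts, and infinite-sites
#' mutations are placed on four-fold-degenerate third positions of a random
#' reference CDS. Sampled individuals are females (two copies in both
#' modes), mirroring the female sampling of the study design; heterozygous
#' sites are IUPAC-coded.
#'
#' @param n_males,n_females breeding males and females (>= 1).
#' @param mode `"X"` or `"autosome"`.
#' @param theta pairwise diversity per silent site expected for an
#'   autosomal locus at equal sex numbers; the per-generation mutation rate
#'   is `theta / (2 * autosomal copy number)` in both modes (equal mutation
#'   rates on X and autosomes).
#' @param n_individuals diploid individuals sampled.
#' @param L gene length in codons.
#' @param seed integer seed; bit-for-bit reproducible.
#' @return a `diploid_panel`: character matrix `seq` (individuals x
#'   nucleotide sites, IUPAC-coded), `ref_cds` string, `silent_sites`
#'   positions, plus the generating truth in attributes.
#' @export
simulate_population <- function(n_males, n_females, mode, theta,
                                n_individuals, L, seed = 1) {
  if (n_males < 1 || n_females < 1) stop("need at least one of each sex")
  if (n_individuals > n_females)
    stop("sample of ", n_individuals,
         " exceeds the number of females (", n_females, ")")
  gcd <- genetic_code()
  p2 <- pair_coal_prob(mode, n_males, n_females)
  mu <- theta / (2 * (2 * (n_males + n_females)))
  k0 <- 2L * n_individuals
  with_seed(seed, {
    ref_idx <- sample.int(61, L, replace = TRUE)
    ref <- strsplit(paste(gcd$codons[ref_idx], collapse = ""), "")[[1]]
    silent <- which(rep(gcd$fourfold[ref_idx], each = 3) &
                      (seq_len(3 * L) %% 3 == 0))
    # genealogy: active lineages hold tip sets; record branches on merge
    act_tips <- as.list(seq_len(k0))
    act_birth <- rep(0, k0)
    now <- 0
    br_tips <- list(); br_len <- numeric(0)
    k <- k0
    while (k > 1) {
      now <- now + stats::rexp(1, rate = choose(k, 2) * p2)
      pair <- sample.int(k, 2)
      i <- min(pair); j <- max(pair)
      br_tips <- c(br_tips, act_tips[c(i, j)])
      br_len <- c(br_len, now - act_birth[c(i, j)])
      act_tips[[i]] <- c(act_tips[[i]], act_tips[[j]])
      act_birth[i] <- now
      act_tips[[j]] <- NULL
      act_birth <- act_birth[-j]
      k <- k - 1L
    }
    total_len <- sum(br_len)
    n_mut <- if (theta > 0)
      stats::rpois(1, mu * length(silent) * total_len) else 0L
    if (n_mut > length(silent)) {
      warning("more mutations than silent sites; capping (infinite sites)")
      n_mut <- length(silent)
    }
    alleles <- matrix(rep(ref, k0), nrow = k0, byrow = TRUE)
    if (n_mut > 0) {
      mb <- sample.int(length(br_len), n_mut, replace = TRUE, prob = br_len)
      ms <- silent[sample.int(length(silent), n_mut)]
      for (m in seq_len(n_mut)) {
        pos <- ms[m]
        derived <- sample(setdiff(.CODE_NT, ref[pos]), 1)
        alleles[br_tips[[mb[m]]], pos] <- derived
      }
    }
    iupac <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
               AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")
    seqm <- matrix("", n_individuals, 3 * L)
    for (i in seq_len(n_individuals)) {
      a <- alleles[2 * i - 1, ]; b <- alleles[2 * i, ]
      s <- a
      het <- a != b
      s[het] <- iupac[paste0(a[het], b[het])]
      seqm[i, ] <- s
    }
    rownames(seqm) <- sprintf("ind%02d", seq_len(n_individuals))
    structure(list(individuals = rownames(seqm), seq = seqm,
                   ref_cds = paste(ref, collapse = ""),
                   silent_sites = silent),
              class = "diploid_panel",
              mode = mode, theta = theta, total_branch_gens = total_len,
              n_mutations = n_mut)
  })
}

#' Write a diploid panel as IUPAC-coded FASTA
#' @param panel a `diploid_panel`.
#' @param path output file.
#' @export
write_diploid_fasta <- function(panel, path) {
  lines <- character(0)
  for (i in seq_along(panel$individuals)) {
    lines <- c(lines, paste0(">", panel$individuals[i]),
               paste(panel$seq[i, ], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a sexed expression matrix
#'
#' Log-normal expression for `n_genes` genes over sexed individuals;
#' a `biased_fraction` of genes receives a female multiplier `effect`. The
#' truth is returned alongside, never read by the flagging stage.
#'
#' @param n_genes number of genes.
#' @param n_males,n_females individuals per sex (defaults 23 / 34, the
#'   study's sample sizes).
#' @param biased_fraction fraction of genes simulated female-biased.
#' @param effect multiplicative female effect for biased genes.
#' @param seed integer seed.
#' @param path optional TSV output (genes x individuals, with a `sex` header
#'   row).
#' @return list with `expr` (matrix), `sex` (factor), `truth` (logical).
#' @export
simulate_expression <- function(n_genes, n_males = 23, n_females = 34,
                                biased_fraction = 0.1, effect = 4,
                                seed = 1, path = NULL) {
  if (n_males < 2 || n_females < 2) stop("need >= 2 individuals per sex")
  with_seed(seed, {
    sex <- factor(c(rep("male", n_males), rep("female", n_females)),
                  levels = c("male", "female"))
    biased <- stats::runif(n_genes) < biased_fraction
    meanlog <- stats::rnorm(n_genes, 3, 1)
    expr <- matrix(0, n_genes, n_males + n_females,
                   dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                   sprintf("%s%02d",
                                           substr(as.character(sex), 1, 1),
                                           seq_along(sex))))
    for (g in seq_len(n_genes)) {
      mult <- ifelse(sex == "female" & biased[g], effect, 1)
      expr[g, ] <- stats::rlnorm(ncol(expr), meanlog[g], 0.5) * mult
    }
    if (!is.null(path)) {
      df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(paste0("# sex: ", paste(sex, collapse = ",")),
                 paste0(path, ".sex"))
    }
    list(expr = expr, sex = sex, truth = biased)
  })
}
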