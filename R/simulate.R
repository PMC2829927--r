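#' Simulate nuclear families under the liability-threshold model
#'
#' Generates two-sibling nuclear families. Per locus, both parents' allele
#' pairs are drawn from Hardy--Weinberg proportions and each sibling
#' inherits one Mendelian-sampled allele from each parent, which induces the
#' exact sibpair genotype dependence (expected copy-count correlation 0.5).
#' Each sibling's liability is the sum of its centered genotype values and a
#' residual of variance \eqn{1 - \sum_v VE_v} (total liability variance 1)
#' built from a polygenic part split into shared and independent halves
#' (\eqn{0.5\sigma^2_{poly}} each), a shared family environment
#' (\eqn{\sigma^2_c}) and a nonshared component (\eqn{\sigma^2_e}), the
#' three fractions partitioning the residual. A sibling is affected when
#' its liability reaches the model threshold.
#'
#' Simulation proceeds in fixed internal blocks of \code{1e5} families;
#' block \code{b} is seeded with \code{seed + b}, so results are
#' reproducible and independent of any outer chunking. The caller's RNG
#' state is preserved.
#'
#' @param model a \code{\link{disease_model}}.
#' @param n number of families.
#' @param seed integer seed (keep below 2^31 - number of blocks).
#' @return an object of class \code{family_dataset}: list with integer
#'   matrices \code{genotypes_index}, \code{genotypes_sib} (families x
#'   loci), numeric \code{liability_index}, \code{liability_sib}, logical
#'   \code{affected_index}, \code{affected_sib}, plus \code{scheme} and
#'   \code{seed}.
#' @export
simulate_families <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "disease_model"), n >= 1)
  blocks <- simulate_blocks(model, n, seed, start_block = 1L)
  out <- bind_family_blocks(blocks$data)
  out$scheme <- "unselected"
  out$seed <- seed
  out
}

.block_size <- 100000L

# simulate ceiling(n / block) blocks starting at start_block; returns the
# list of per-block datasets (trimmed to n total) and the next block index
simulate_blocks <- function(model, n, seed, start_block) {
  nb <- ceiling(n / .block_size)
  data <- vector("list", nb)
  for (b in seq_len(nb)) {
    size <- if (b < nb) .block_size else n - (nb - 1L) * .block_size
    data[[b]] <- simulate_block(model, size,
                                seed + (start_block + b - 2L))
  }
  list(data = data, next_block = start_block + nb)
}

simulate_block <- function(model, n, block_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(block_seed %% .Machine$integer.max)
  v <- model$variants
  nv <- nrow(v)
  gi <- matrix(0L, n, nv)
  gs <- matrix(0L, n, nv)
  mu_i <- numeric(n); mu_s <- numeric(n)
  for (l in seq_len(nv)) {
    p <- v$raf[l]
    m1 <- rbinom(n, 1L, p); m2 <- rbinom(n, 1L, p)
    f1 <- rbinom(n, 1L, p); f2 <- rbinom(n, 1L, p)
    ti <- runif(n) < 0.5; ui <- runif(n) < 0.5
    ts <- runif(n) < 0.5; us <- runif(n) < 0.5
    gi[, l] <- ifelse(ti, m1, m2) + ifelse(ui, f1, f2)
    gs[, l] <- ifelse(ts, m1, m2) + ifelse(us, f1, f2)
    mu_i <- mu_i + (gi[, l] - 2 * p) * v$a[l]
    mu_s <- mu_s + (gs[, l] - 2 * p) * v$a[l]
  }
  comp <- model$components
  # residual variance is 1 - total VE (total liability variance is 1);
  # the poly/shared_env/nonshared fractions partition that residual
  rv <- model$residual_scale^2
  shared <- rnorm(n, 0, sqrt(rv * (0.5 * comp$poly + comp$shared_env)))
  uniq_sd <- sqrt(rv * (0.5 * comp$poly + comp$nonshared))
  li <- mu_i + shared + rnorm(n, 0, uniq_sd)
  ls <- mu_s + shared + rnorm(n, 0, uniq_sd)
  t <- model$threshold
  list(genotypes_index = gi, genotypes_sib = gs,
       liability_index = li, liability_sib = ls,
       affected_index = li >= t, affected_sib = ls >= t)
}

bind_family_blocks <- function(blocks) {
  out <- list(
    genotypes_index = do.call(rbind, lapply(blocks, `[[`, "genotypes_index")),
    genotypes_sib = do.call(rbind, lapply(blocks, `[[`, "genotypes_sib")),
    liability_index = unlist(lapply(blocks, `[[`, "liability_index"), use.names = FALSE),
    liability_sib = unlist(lapply(blocks, `[[`, "liability_sib"), use.names = FALSE),
    affected_index = unlist(lapply(blocks, `[[`, "affected_index"), use.names = FALSE),
    affected_sib = unlist(lapply(blocks, `[[`, "affected_sib"), use.names = FALSE)
  )
  class(out) <- "family_dataset"
  out
}

#' Simulate families ascertained for an affected sibling
#'
#' Rejection sampling: simulates families in chunks and retains those whose
#' designated sibling (the "S" slot) is affected, until \code{n_target}
#' families are collected. The expected acceptance rate is the realized
#' prevalence (about \eqn{k}), so roughly \code{n_target / k} families are
#' generated. With \code{at_least_one = TRUE} families are retained when
#' either sibling is affected (and the affected one is rotated into the S
#' slot), the variant used for the genotype-combination inset.
#'
#' @param model a \code{\link{disease_model}}.
#' @param n_target number of retained families.
#' @param seed integer seed.
#' @param chunk families simulated per rejection round (rounded up to whole
#'   internal blocks of 1e5).
#' @param max_chunks safety cap on rejection rounds.
#' @param at_least_one retain on "at least one sibling affected".
#' @return a \code{family_dataset} with \code{scheme = "sib_affected"};
#'   \code{affected_sib} is all-\code{TRUE}. Attribute
#'   \code{acceptance_rate} records the realized rejection-sampling yield.
#' @export
ascertain_sib_affected <- function(model, n_target, seed = 1L,
                                   chunk = 1e6, max_chunks = 1000L,
                                   at_least_one = FALSE) {
  stopifnot(inherits(model, "disease_model"), n_target >= 1)
  kept <- list()
  n_kept <- 0L
  n_seen <- 0
  next_block <- 1L
  rounds <- 0L
  while (n_kept < n_target) {
    rounds <- rounds + 1L
    if (rounds > max_chunks)
      stop("sibrisk_runtime_error: ascertainment acceptance rate too low (",
           signif(n_kept / max(1, n_seen), 3), " after ", n_seen,
           " families); check the model prevalence", call. = FALSE)
    sim <- simulate_blocks(model, chunk, seed, next_block)
    next_block <- sim$next_block
    for (blk in sim$data) {
      n_seen <- n_seen + length(blk$affected_sib)
      keep <- if (at_least_one) blk$affected_sib | blk$affected_index
              else blk$affected_sib
      if (!any(keep)) next
      sub <- lapply(blk, function(x)
        if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep])
      if (at_least_one) {
        # rotate an affected sibling into the S slot (index stays index
        # unless only the index is affected, in which case the pair swaps)
        swap <- !sub$affected_sib
        if (any(swap)) {
          fields <- list(c("genotypes_index", "genotypes_sib"),
                         c("liability_index", "liability_sib"),
                         c("affected_index", "affected_sib"))
          for (f in fields) {
            tmp <- sub[[f[1]]]
            if (is.matrix(tmp)) {
              sub[[f[1]]][swap, ] <- sub[[f[2]]][swap, ]
              sub[[f[2]]][swap, ] <- tmp[swap, ]
            } else {
              sub[[f[1]]][swap] <- sub[[f[2]]][swap]
              sub[[f[2]]][swap] <- tmp[swap]
            }
          }
        }
      }
      kept[[length(kept) + 1L]] <- sub
      n_kept <- n_kept + sum(keep)
    }
  }
  out <- bind_family_blocks(kept)
  if (n_kept > n_target) {
    out[1:6] <- lapply(out[1:6], function(x)
      if (is.matrix(x)) x[seq_len(n_target), , drop = FALSE]
      else x[seq_len(n_target)])
  }
  out$scheme <- if (at_least_one) "at_least_one_affected" else "sib_affected"
  out$seed <- seed
  attr(out, "acceptance_rate") <- n_kept / n_seen
  out
}

#' @export
print.family_dataset <- function(x, ...) {
  n <- length(x$affected_index)
  cat(sprintf("family_dataset: %d families, %d loci, scheme '%s' (seed %s)\n",
              n, ncol(x$genotypes_index), x$scheme, format(x$seed)))
  cat(sprintf("  index case rate %.4g, sibling case rate %.4g\n",
              mean(x$affected_index), mean(x$affected_sib)))
  invisible(x)
}

#' Write a family dataset as TSV with a JSON sidecar
#'
#' One row per family: per-locus copy counts for both siblings, liabilities
#' and disease states. A \code{<path>.json} sidecar records the scheme, the
#' seed and the generating model. Use a \code{.gz} suffix for compressed
#' output.
#'
#' @param dataset a \code{family_dataset}.
#' @param path output TSV path.
#' @param model optional generating \code{\link{disease_model}} recorded in
#'   the sidecar.
#' @export
write_family_dataset <- function(dataset, path, model = NULL) {
  stopifnot(inherits(dataset, "family_dataset"))
  nv <- ncol(dataset$genotypes_index)
  df <- data.frame(dataset$genotypes_index, dataset$genotypes_sib,
                   liability_index = dataset$liability_index,
                   liability_sib = dataset$liability_sib,
                   affected_index = as.integer(dataset$affected_index),
                   affected_sib = as.integer(dataset$affected_sib))
  names(df)[seq_len(2 * nv)] <- c(paste0("gi_", seq_len(nv)),
                                  paste0("gs_", seq_len(nv)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  side <- list(scheme = dataset$scheme, seed = dataset$seed,
               n = length(dataset$affected_index))
  if (!is.null(model))
    side$model <- list(prevalence = model$prevalence,
                       components = unclass(model$components)[1:3],
                       variants = model$variants)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
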