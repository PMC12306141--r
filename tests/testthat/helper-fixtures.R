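# fixture builders used by several test files

toy_manifest <- function(n_ed = 4, n_sui = 4) {
  ids <- c(paste0("ed", seq_len(n_ed)), paste0("sui", seq_len(n_sui)))
  as_ema_manifest(data.frame(
    item_id = ids, label = ids, prompt = paste("prompt for", ids),
    community = rep(c("ED", "SUI"), c(n_ed, n_sui)),
    stringsAsFactors = FALSE))
}

# dataset from an (n_scheduled x items) score matrix; NA = missing
dataset_from_matrix <- function(m, n_days, beeps_per_day,
                                manifest = NULL, id = "toy") {
  manifest <- manifest %||% toy_manifest(ceiling(ncol(m) / 2),
                                         floor(ncol(m) / 2))
  manifest <- manifest[seq_len(ncol(m)), ]
  colnames(m) <- manifest$item_id
  sch <- ema_schedule(n_days, beeps_per_day)
  df <- data.frame(day = rep(seq_len(n_days), each = beeps_per_day),
                   beep = rep(seq_len(beeps_per_day), times = n_days))
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  ema_dataset(id, manifest, sch, df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standardized lagged pairs straight from a latent VAR(1) chain
pairs_from_truth <- function(truth, n_pairs, seed) {
  x <- simulate_latent(truth, n_pairs + 1L, seed = seed)
  lagged_pairs(x[seq_len(n_pairs), , drop = FALSE],
               x[1L + seq_len(n_pairs), , drop = FALSE],
               nodes = truth$nodes)
}

# hand-entered centrality table in the published Patient-1 pattern:
# feel_fat and fear_weight lead contemporaneous strength; skip_meals_urge
# is top-2 on three statistics; worth_weight second on bridge OutStrength
patient1_centrality <- function() {
  data.frame(
    node = c("feel_fat", "fear_weight", "worth_weight", "skip_meals_urge",
             "desire_live", "fear_death", "reasons_die", "passive_ideation_1"),
    community = rep(c("ED", "SUI"), each = 4),
    contemporaneous_strength = c(0.92, 0.83, 0.40, 0.35, 0.30, 0.25, 0.20, 0.45),
    contemporaneous_bridge_strength = c(0.05, 0.04, 0.02, 0.10, 0.06, 0.03,
                                        0.01, 0.49),
    in_strength = c(0.30, 0.25, 0.20, 0.15, 0.10, 0.08, 0.06, 0.04),
    out_strength = c(0.39, 0.20, 0.15, 1.10, 0.10, 0.05, 0.08, 0.12),
    bridge_in_strength = c(0.05, 0.04, 0.03, 0.02, 0.01, 0.02, 0.03, 0.04),
    bridge_out_strength = c(0.10, 0.05, 0.18, 0.49, 0.02, 0.01, 0.03, 0.04),
    stringsAsFactors = FALSE)
}
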