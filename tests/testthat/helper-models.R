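# Shared end-to-end artifacts: the desk-scale cohort split and the trained
# edema-target model, cached so several test files can interrogate them.

e2e_split <- function() {
  ids <- sprintf("phantom-%03d", 1:12)
  make_split(ids, fractions = c(8, 2, 2), seed = 406)
}

# {p, q, FLAIR, T1c} -> FLAIR-mask, trained with augmentation for >= 5 epochs
trained_flair_run <- function() {
  cached("trained_flair_run", {
    co <- study_cohort()
    ids <- vapply(co, function(e) e$study$study_id, character(1))
    split <- e2e_split()
    sp <- model_spec(7)
    cfg <- small_network_config(sp$input_channels)
    tc <- train_config(epochs = 5, segments_per_epoch = 100, batch_size = 10,
                       learning_rate = 1e-3, augment = TRUE, seed = 106)
    net <- build_network(cfg, seed = 106)
    tr <- train_model(net, co[ids %in% split$train_ids],
                      co[ids %in% split$val_ids], sp, tc)
    list(run = tr, untrained = net, spec = sp, cohort = co, split = split,
         ids = ids)
  })
}
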