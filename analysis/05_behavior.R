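#!/usr/bin/env Rscript
# Behavioral plasticity scores on simulated cohorts: a cocaine-paired
# CPP group against a saline (null) group, per-level percent PPI, and
# novel-object preference at short-term test against a null training
# session.

suppressMessages(library(tunedrift))

seed <- 52
n <- 12   # animals per group

coc <- gen_behavior(list(cpp = list(n = n, effect = 0.25)), seed = seed)
sal <- gen_behavior(list(cpp = list(n = n, effect = 0)), seed = seed + 1)
cpp <- rbind(data.frame(group = "cocaine", coc$cpp),
             data.frame(group = "saline", sal$cpp))
cpp$score <- cpp_score(cpp$time_cocaine_s, cpp$time_saline_s)
write.csv(cpp, "results/behavior_cpp.csv", row.names = FALSE)
cat(sprintf("CPP: cocaine group mean score %.2f, saline group %.2f (n = %d each)\n",
            mean(cpp$score[cpp$group == "cocaine"]),
            mean(cpp$score[cpp$group == "saline"]), n))

ppi <- gen_behavior(list(ppi = list()), seed = seed + 2)
tab <- ppi_table(ppi$ppi)
write.csv(tab, "results/behavior_ppi.csv", row.names = FALSE)
cat("PPI by prepulse level (dB above background):\n")
for (i in seq_len(nrow(tab)))
  cat(sprintf("  +%g dB: %.1f%% (expected %.0f%%)\n", tab$prepulse_db[i],
              tab$ppi_percent[i],
              ppi$expected$ppi_percent[as.character(tab$prepulse_db[i])]))

train <- gen_behavior(list(nor = list(n = n, effect = 0)), seed = seed + 3)
stm <- gen_behavior(list(nor = list(n = n, effect = 0.3)), seed = seed + 4)
nor <- rbind(data.frame(test = "training", train$nor),
             data.frame(test = "STM", stm$nor))
nor$preference <- nor_preference(nor$time_novel_s, nor$time_familiar_s)
write.csv(nor, "results/behavior_nor.csv", row.names = FALSE)
cat(sprintf("NOR: training preference %.2f, STM preference %.2f (paired t p = %.3f)\n",
            mean(nor$preference[nor$test == "training"]),
            mean(nor$preference[nor$test == "STM"]),
            t.test(nor$preference[nor$test == "STM"],
                   nor$preference[nor$test == "training"], paired = TRUE)$p.value))
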