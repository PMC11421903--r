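#!/usr/bin/env Rscript

## Stage 3 -- social-tier inference from sighting data.
##
## Simple-ratio association indices between all adult females (individuals
## seen < 20 times excluded), Ward clustering, automated knot detection on
## the cumulative-bifurcation curve to cut core groups, then the same
## procedure on the matriarchs only to assemble bond groups.

suppressMessages(library(rumblesig))

dataset <- readRDS("scratch/dataset.rds")
cfg <- dataset$config
ages <- setNames(dataset$truth$callers$age_years,
                 dataset$truth$callers$caller_id)

assoc <- association_matrix(dataset$sightings, min_sightings = 20)
partition <- infer_tiers(dataset$sightings, ages, min_sightings = 20)

write_prov_csv(cbind(id = assoc$ids, as.data.frame(assoc$index)),
               "results/association.csv", cfg$seed, cfg)
write_prov_csv(partition$members, "results/partition.csv", cfg$seed, cfg)

cat(sprintf("association matrix over %d individuals (median index %.3f)\n",
            length(assoc$ids), median(assoc$index[upper.tri(assoc$index)])))
cat(sprintf("inferred %d core groups (cut %.3f) in %d bond groups\n",
            length(unique(partition$members$core)),
            partition$core_cut_height,
            length(unique(partition$members$bond))))

## compare against the simulator's ground truth
m <- merge(partition$members, dataset$truth$callers,
           by.x = "id", by.y = "caller_id")
cat(sprintf("recovery vs ground truth: core ARI = %.3f, bond ARI = %.3f\n",
            mclust::adjustedRandIndex(m$core.x, m$core.y),
            mclust::adjustedRandIndex(m$bond.x, m$bond.y)))
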