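column,type,unit,description
dish_id,text,,dish identifier; shared by the germination and seedling series of one dish
species,text,,species name
accession,text,,seed-lot (population) identifier
region,text,,collection region label
replicate,integer,,replicate-experiment index (one dish per treatment per replicate); optional and defaults to 1
stage,enum,,germination or seedling
treatment_kind,enum,,temperature or osmoticum
treatment_value,numeric,degC or MPa,constant incubation temperature or PEG-8000 water potential
time_h,numeric,hours,elapsed time of the scoring observation
cum_count,integer,seeds,cumulative count of seeds past the stage at time_h
n_sown,integer,seeds,seeds sown in the dish
n_viable_ungerminated,integer,seeds,cut-test viable seeds that never germinated
n_dead,integer,seeds,cut-test dead seeds
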