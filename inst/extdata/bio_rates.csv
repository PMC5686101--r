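species,genome_mbp,rate_min,rate_max,basis,unit,source_key
Human,3080,1e-8,2.5e-8,per_base,per_generation,49;56;57
Human,3080,175,175,per_genome,per_generation,49
Human,3080,5e-11,6e-2,per_base,per_cell_division,46;57
Human,3080,0.16,0.16,per_genome,per_cell_division,46
Human (Y chromosome),58,3e-8,3e-8,per_base,per_generation,61
Human; chimpanzee,3080,3,3,per_genome,per_generation,50
D. melanogaster,120,4.65e-9,6.2e-8,per_base,per_generation,47;48;51;57
D. melanogaster,120,0.99,1.2,per_genome,per_generation,47;50
Drosophila spp.,120,7e-2,7e-2,per_genome,per_generation,50
D. melanogaster,120,1.3e-10,3.4e-10,per_base,per_cell_division,46;57
Quail; chicken,1050,0.49,0.49,per_genome,per_generation,50
Sheep; cow,2870,0.9,0.9,per_genome,per_generation,50
Old World Monkey,NA,1.9,1.9,per_genome,per_generation,50
Mouse; rat,2640,0.91,0.91,per_genome,per_generation,50
Mouse,2640,1.8e-10,1.8e-10,per_base,per_cell_division,46
Mouse,2640,1.1e-8,1.1e-8,per_base,per_generation,46
S. cerevisiae,12.1,3.3e-10,3.3e-10,per_base,per_generation,57
S. cerevisiae,12.1,3.3e-10,3.3e-10,per_base,per_cell_division,52
Average mammalian,NA,2.2e-9,2.2e-9,per_base,per_genome_year,55
Mammalian upper bound,NA,2.61e-9,2.61e-9,per_base,per_genome_year,55
C. elegans,100,8.4e-9,2.1e-8,per_base,per_generation,47;53;58
C. elegans,100,2.9,2.9,per_genome,per_generation,52
A. thaliana,157,7.1e-9,7.1e-9,per_base,per_generation,54
A. thaliana,157,6.5e-9,6.5e-9,per_base,per_generation,58
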