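description,population_size,gene_length,gene_count,scale,crossovers,chromosomes,cmr,ci_low,ci_high
canonical landscape plateau (S=1; 1 crossover),1000,1000,1,1,1,1,0.00028,NA,NA
scale S=10 plateau,1000,1000,1,10,1,1,0.00087,NA,NA
5 crossovers plateau,1000,1000,1,1,5,1,0.0037,NA,NA
gene length 30,900,30,1,1,1,1,9.37e-3,9.317e-3,9.423e-3
gene length 150000,900,150000,1,1,1,1,1.84e-6,1.834e-6,1.846e-6
scale S=10,900,1000,1,10,1,1,8.66e-4,8.621e-4,8.699e-4
scale S=1,900,1000,1,1,1,1,2.75e-4,2.740e-4,2.760e-4
5 crossovers,900,1000,1,1,5,1,3.91e-3,3.866e-3,3.954e-3
10 chromosomes,900,1000,1,1,1,10,4.73e-3,4.703e-3,4.757e-3
8192 genes,80,1000,8192,1,1,1,5.26e-8,4.100e-8,6.400e-8
8192 genes,10,1000,8192,1,1,1,1.25e-7,1.000e-7,1.500e-7
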