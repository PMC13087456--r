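individual_id,family_id,gene,sex,genetic_ancestry,age_last_assessment_years,deceased,bw_z,age_dx_weeks,glucose_dx_mmol_l,hba1c_mmol_mol,insulin_dose_u_kg_day,islet_autoantibodies,autoantibody_titer,autoantibody_threshold,immune_features,microcephaly,developmental_delay,additional_features,allele1_n,allele2_n,allele1_g,allele2_g,zygosity,chromosome,transcript_accession
A.II-1,A,RNU6ATAC,F,EAS,0.3,yes,-2.26,13,28.3,N/A,N/A,N/A,N/A,N/A,sepsis;atopic dermatitis;B cell lymphopenia;low IgA;low IgG;hypothyroidism,no,N/A,diarrhea;facial dysmorphism,6G>A,6G>A,134164559C>T,134164559C>T,homozygous,chr9,NR_023344.1
A.II-2,A,RNU6ATAC,F,EAS,0.3,yes,-3.17,11,33,N/A,N/A,N/A,N/A,N/A,B cell lymphopenia;hypothyroidism,no,N/A,jaundice;elevated unconjugated bilirubin,6G>A,6G>A,134164559C>T,134164559C>T,homozygous,chr9,NR_023344.1
B.II-1,B,RNU6ATAC,M,SAS,0.3,yes,-1.72,17,41,N/A,1.5,GADA positive,52,>11,agammaglobulinemia,no,N/A,none reported,71C>T,71C>T,134164494G>A,134164494G>A,homozygous,chr9,NR_023344.1
C.II-1,C,RNU6ATAC,M,MID,5,no,N/R,36,N/R,N/R,N/R,N/R,N/R,N/R,hypogammaglobulinemia;immunodeficiency,N/R,N/R,epiphyseal dysplasia;elevated liver enzymes,43G>A,43G>A,134164522C>T,134164522C>T,homozygous,chr9,NR_023344.1
D.II-1,D,RNU6ATAC,M,MID,4,no,0.06,5,25,111,0.7,negative,N/A,N/A,thyroiditis;alopecia,no,no,none reported,4T>C,68C>A,134164561A>G,134164497G>T,compound_het,chr9,NR_023344.1
D.II-2,D,RNU6ATAC,F,MID,14,no,0.06,110,25,108,N/R,negative,N/A,N/A,N/R,no,no,severe growth retardation;delayed puberty,4T>C,68C>A,134164561A>G,134164497G>T,compound_het,chr9,NR_023344.1
D.II-3,D,RNU6ATAC,M,MID,9,no,N/R,260,N/R,118,N/R,GADA positive,98,>11,alopecia;vitiligo;thyroiditis,no,no,none reported,4T>C,68C>A,134164561A>G,134164497G>T,compound_het,chr9,NR_023344.1
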