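# nif gene-class catalog of the seven gill symbiont species
# sp1, sp2: all 17 classes; sp4: all but nifJ; sp5: nifJ only;
# sp3, sp6, sp7: none
taxon_id	element_type	element_id	substrate_tags
sp1	nif_class	nifH	
sp1	nif_class	nifD	
sp1	nif_class	nifK	
sp1	nif_class	nifE	
sp1	nif_class	nifN	
sp1	nif_class	nifB	
sp1	nif_class	nifA	
sp1	nif_class	nifL	
sp1	nif_class	nifM	
sp1	nif_class	nifS	
sp1	nif_class	nifT	
sp1	nif_class	nifU	
sp1	nif_class	nifV	
sp1	nif_class	nifW	
sp1	nif_class	nifQ	
sp1	nif_class	nifZ	
sp1	nif_class	nifJ	
sp2	nif_class	nifH	
sp2	nif_class	nifD	
sp2	nif_class	nifK	
sp2	nif_class	nifE	
sp2	nif_class	nifN	
sp2	nif_class	nifB	
sp2	nif_class	nifA	
sp2	nif_class	nifL	
sp2	nif_class	nifM	
sp2	nif_class	nifS	
sp2	nif_class	nifT	
sp2	nif_class	nifU	
sp2	nif_class	nifV	
sp2	nif_class	nifW	
sp2	nif_class	nifQ	
sp2	nif_class	nifZ	
sp2	nif_class	nifJ	
sp4	nif_class	nifH	
sp4	nif_class	nifD	
sp4	nif_class	nifK	
sp4	nif_class	nifE	
sp4	nif_class	nifN	
sp4	nif_class	nifB	
sp4	nif_class	nifA	
sp4	nif_class	nifL	
sp4	nif_class	nifM	
sp4	nif_class	nifS	
sp4	nif_class	nifT	
sp4	nif_class	nifU	
sp4	nif_class	nifV	
sp4	nif_class	nifW	
sp4	nif_class	nifQ	
sp4	nif_class	nifZ	
sp5	nif_class	nifJ	
sp3	none		
sp6	none		
sp7	none		
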