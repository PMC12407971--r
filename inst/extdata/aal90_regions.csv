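name,abbr
Precentral gyrus,PreCG
Superior frontal gyrus (dorsolateral),SFGdor
Superior frontal gyrus (orbital),ORBsup
Middle frontal gyrus,MFG
Middle frontal gyrus (orbital),ORBmid
Inferior frontal gyrus (opercular),IFGoperc
Inferior frontal gyrus (triangular),IFGtriang
Inferior frontal gyrus (orbital),ORBinf
Rolandic operculum,ROL
Supplementary motor area,SMA
Olfactory cortex,OLF
Superior frontal gyrus (medial),SFGmed
Superior frontal gyrus (medial orbital),ORBsupmed
Rectus gyrus,REC
Insula,INS
Anterior cingulate gyrus,ACG
Median cingulate gyrus,MCG
Posterior cingulate gyrus,PCG
Hippocampus,HIP
Parahippocampal gyrus,PHG
Amygdala,AMYG
Calcarine cortex,CAL
Cuneus,CUN
Lingual gyrus,LING
Superior occipital gyrus,SOG
Middle occipital gyrus,MOG
Inferior occipital gyrus,IOG
Fusiform gyrus,FFG
Postcentral gyrus,PoCG
Superior parietal gyrus,SPG
Inferior parietal gyrus,IPG
Supramarginal gyrus,SMG
Angular gyrus,ANG
Precuneus,PCUN
Paracentral lobule,PCL
Caudate,CAU
Putamen,PUT
Pallidum,PAL
Thalamus,THA
Heschl gyrus,HES
Superior temporal gyrus,STG
Temporal pole (superior),TPOsup
Middle temporal gyrus,MTG
Temporal pole (middle),TPOmid
Inferior temporal gyrus,ITG
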