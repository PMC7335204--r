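short_name	full_name	source_atlas	lateralized
mPFC	medial prefrontal cortex	Destrieux	yes
dlPFC	dorsolateral prefrontal cortex	Brodmann	yes
vlPFC	ventrolateral prefrontal cortex	Destrieux	yes
pACC	perigenual anterior cingulate cortex	Destrieux	yes
sACC	subgenual anterior cingulate cortex	Destrieux	yes
aMCC	anterior middle cingulate cortex	Destrieux	yes
pMCC	posterior middle cingulate cortex	Destrieux	yes
PCC	posterior cingulate cortex	Destrieux	yes
insula_anterior	anterior insula	Larsson2012	yes
insula_mid	middle insula	Larsson2012	yes
insula_posterior	posterior insula	Larsson2012	yes
amygdala	amygdala	AAL	yes
parahippo	parahippocampal gyrus	Destrieux	yes
hippocampus	hippocampus	Destrieux	yes
SII	secondary somatosensory cortex	Destrieux	yes
SI	primary somatosensory cortex	Destrieux	yes
LTC	lateral temporal cortex	Destrieux	yes
IPL	inferior parietal lobule	Destrieux	yes
precuneus	precuneus	Destrieux	yes
Angular	angular gyrus	Destrieux	yes
putamen	putamen	AAL	yes
thalamus	thalamus	AAL	yes
PAG	periaqueductal gray	sphere_6mm_0_-28_-8	no
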