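# Synthetic toy S-value matrix for tests and examples (NOT phantom-derived).
# Units: uSv/MBq per MBq.h of residence time. Diagonal self-dose dominates;
# small cross-terms couple neighbouring abdominal organs; every target
# receives a small contribution from the remainder of body.
target,liver,lungs,small_intestine,gall_bladder,stomach,heart,pancreas,kidneys,spleen,brain,red_marrow,urinary_bladder,remainder
liver,40,1,2,4,2,1,3,2,1,0,1,0.2,2
lungs,1,35,0.2,0.5,0.5,4,0.5,0.3,0.5,0.1,1,0.05,2
small_intestine,2,0.2,45,3,2,0.2,3,2,1,0,1,2,2
gall_bladder,4,0.5,3,60,2,0.3,4,2,1,0,1,0.5,2
stomach,2,0.5,2,2,38,0.5,4,2,3,0,1,0.2,2
heart,1,4,0.2,0.3,0.5,42,0.5,0.3,0.5,0.1,1,0.05,2
pancreas,3,0.5,3,4,4,0.5,55,3,3,0,1,0.2,2
kidneys,2,0.3,2,2,2,0.3,3,48,2,0,1,1,2
spleen,1,0.5,1,1,3,0.5,3,2,50,0,1,0.2,2
brain,0,0.1,0,0,0,0.1,0,0,0,30,0.5,0,1
red_marrow,1,1,1,1,1,1,1,1,1,0.5,20,1,2
urinary_bladder,0.2,0.05,2,0.5,0.2,0.05,0.2,1,0.2,0,1,55,2
remainder,2,2,2,2,2,2,2,2,2,1,2,2,8
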