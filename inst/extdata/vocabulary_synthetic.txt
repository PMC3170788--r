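# Synthetic reconstruction of a 90-term modality keyword vocabulary:
# modality names, acronyms, and common caption terms indicative of the
# acquisition technology. Not a published list; supply your own file to
# load_vocabulary()/the vocabulary_path config key to replace it.
# One keyword (or space-separated phrase) per line.
ct
mr
mri
pet
nm
us
xr
gx
px
scan
tomography
computed
magnetic
resonance
ultrasound
ultrasonography
doppler
radiograph
radiography
xray
roentgen
nuclear
scintigraphy
scintigram
spect
positron
emission
fdg
tracer
uptake
t1
t2
flair
gadolinium
contrast
axial
coronal
sagittal
transverse
slice
angiogram
angiography
urethrogram
mammogram
mammography
fluoroscopy
sonogram
echocardiogram
echo
transducer
probe
hounsfield
attenuation
bone
chest
abdomen
brain
skull
spine
pelvis
photograph
photo
endoscopy
endoscopic
gross
specimen
histology
micrograph
microscopy
stain
drawing
diagram
chart
graph
curve
plot
illustration
sketch
schematic
graphic
lateral
oblique
anteroposterior
supine
weighted
sequence
gamma
isotope
technetium
barium
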