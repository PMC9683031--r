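# measurement axes
tumour thickness	measurement_axis	thickness
tumor thickness	measurement_axis	thickness
tumour diameter	measurement_axis	diameter
tumor diameter	measurement_axis	diameter
peripheral clearance	measurement_axis	peripheral
peripheral margin	measurement_axis	peripheral
deep clearance	measurement_axis	deep
deep margin	measurement_axis	deep
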