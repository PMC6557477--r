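Score-to-p-value threshold tables (p = 0.0001) for the five mouse
HOCOMOCO v11 motif models used in the allele-motif scan, transcribed from
the published report. Each *.thr file is a two-column TSV: p-value level,
minimum score.

The full position weight matrices are NOT redistributed here. To run the
scan with the genuine models, download the mono PWM files for
AR(ANDR)_MOUSE.H11MO.1.A, ESR1_MOUSE.H11MO.1.A and
FOXA1/2/3_MOUSE.H11MO.0.A from the HOCOMOCO v11 core mouse collection and
place them in this directory as <NAME>.pwm next to the matching .thr
file; read_pwm() then picks up both.
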