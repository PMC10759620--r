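>synthetic_SWS2_numbering_reference length=350 (synthetic stand-in, not a real opsin)
MSWPLQRLLMHKAMMSRAWQMMINQVKNIILYQCMFEVCLSWRCYLWMTAHFMQHMNIFN
SHDFIHLNGPCGCGYGTNVTDVGRENGHCHTDKALWGKLQDFIPRMSFRCAYNHLLTCWH
IEIYEKWCSMNSNLFWAAHQDCLWRYWLNQCLLMIASYPDIARDESVIVNHEYCLACRII
IGWEFQMCGLEHLIVLHMMMMPNYKIYAQNTKRRKREYGDTKLLYNTRLWAAMYEQTFRL
VFDGKECEVVFCRYTTKVWGFYYWNHDGDNVGEAMGTIWDPSHPGQYNRRPADYAFCMGN
HCPWWPGKNDFTGCTDFDLNSRQKCLTNEHWCLGIEYRHLIGASSYQRGL
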