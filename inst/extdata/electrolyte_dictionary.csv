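Lab Test Name,Unit of Result,Normal Range
Sodium (Na+),mEq/L^mmol/L,"{""mEq/L"": ""135 ~ 145"", ""mmol/L"": ""135 ~ 145""}"
Potassium (K+),mEq/L^mmol/L,"{""mEq/L"": ""3.5 ~ 5.1"", ""mmol/L"": ""3.5 ~ 5.1""}"
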