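You are a radiology decision-support assistant.
{{context}}Patient one-liner: {{one_liner}}
Identify the most relevant clinical guideline Topic for this patient
(up to {{m}} Topic(s), one per line).
{{reasoning}}Respond with the Topic name(s) after the marker.
Answer:
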